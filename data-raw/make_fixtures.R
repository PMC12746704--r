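# Build the packaged fixtures under inst/extdata/.
#
# The xylose/formaldehyde network is constructed from a per-species potential
# table (formation free energies, kJ/mol). Reaction free energies are
# potential differences, so loop closure and forward/reverse consistency hold
# exactly. States and energies reported in the main text are encoded at their
# printed values; species and steps that were considered but whose energies
# are not printed carry synthetic values (hence the _synthetic filename).
# Run from the package root:  Rscript data-raw/make_fixtures.R

devtools::load_all(".", quiet = TRUE)

T0 <- 333.15

# ---- species table: id, role, G (kJ/mol), stoich a,b,c,d -------------------
sp_tab <- read.table(header = TRUE, text = "
id                 role                     G        a b c  d
alpha_xylopyranose sugar_tautomer           0.0      1 0 0  0
HCHO               reference                0.0      0 1 0  0
H2O                reference                0.0      0 0 1  0
H3O+               reference                0.0      0 0 0  1
beta_xylopyranose  sugar_tautomer           10.6     1 0 0  0
beta_xylofuranose  sugar_tautomer           17.4     1 0 0  0
alpha_xylofuranose sugar_tautomer           9.7      1 0 0  0
open_xylose        open_intermediate        20.0     1 0 0  0
RO_apyr            protonated_intermediate  -5.0     1 0 -1 1
RO_bpyr            protonated_intermediate  6.0      1 0 -1 1
RO_afur            protonated_intermediate  12.0     1 0 -1 1
RO_bfur            protonated_intermediate  15.0     1 0 -1 1
6a                 protonated_intermediate  -204.6   1 1 -1 1
8a                 protonated_intermediate  -168.0   1 1 -1 1
M5a                protonated_intermediate  -145.0   1 1 -2 1
Int3_alpha         monoacetal               -89.7    1 1 -1 0
RO3_alpha          open_intermediate        -176.6   1 1 -2 1
M17a               protonated_intermediate  -231.6   1 1 -2 1
Int4_alpha         monoacetal               -78.2    1 1 -1 0
16a                protonated_intermediate  -179.4   1 1 -1 1
18a                protonated_intermediate  -184.4   1 1 -1 1
M11a               protonated_intermediate  -134.2   1 1 -2 1
13b                protonated_intermediate  -167.6   1 1 -1 1
14b                protonated_intermediate  -172.6   1 1 -1 1
M8b                protonated_intermediate  -127.6   1 1 -2 1
Int5_beta          monoacetal               -110.0   1 1 -1 0
Int5_alpha         monoacetal               -95.0    1 1 -1 0
16b                protonated_intermediate  -157.6   1 1 -1 1
17b                protonated_intermediate  -160.6   1 1 -1 1
M12b               protonated_intermediate  -170.6   1 1 -2 1
Int4_beta          monoacetal               -60.0    1 1 -1 0
6b                 protonated_intermediate  -179.4   1 1 -1 1
8b                 protonated_intermediate  -142.0   1 1 -1 1
M5b                protonated_intermediate  -120.0   1 1 -2 1
Int3_beta          monoacetal               -47.3    1 1 -1 0
RO3_beta           open_intermediate        -107.3   1 1 -2 1
M16b               protonated_intermediate  -147.3   1 1 -2 1
25a                protonated_intermediate  -308.8   1 2 -2 1
26a                protonated_intermediate  -278.8   1 2 -2 1
M15a               protonated_intermediate  -268.8   1 2 -3 1
DFX                diacetal                 -330.0   1 2 -2 0
23a                protonated_intermediate  -305.0   1 2 -2 1
24a                protonated_intermediate  -310.0   1 2 -2 1
M14a               protonated_intermediate  -290.0   1 2 -3 1
Int6a              monoacetal               -285.0   1 2 -2 0
M1a                protonated_intermediate  -60.0    1 1 -1 1
M2a                protonated_intermediate  -50.0    1 1 -1 1
M3a                protonated_intermediate  -55.0    1 1 -2 1
Int1_alpha         monoacetal               -90.0    1 1 -1 0
RO1_alpha          open_intermediate        -20.0    1 1 -2 1
M6a                protonated_intermediate  -55.0    1 1 -1 1
M7a                protonated_intermediate  -45.0    1 1 -1 1
M9a                protonated_intermediate  -50.0    1 1 -2 1
Int2_alpha         monoacetal               -85.0    1 1 -1 0
RO2_alpha          open_intermediate        -15.0    1 1 -2 1
M1b                protonated_intermediate  -45.0    1 1 -1 1
M2b                protonated_intermediate  -35.0    1 1 -1 1
M3b                protonated_intermediate  -40.0    1 1 -2 1
Int1_beta          monoacetal               -75.0    1 1 -1 0
RO1_beta           open_intermediate        -10.0    1 1 -2 1
M6b                protonated_intermediate  -40.0    1 1 -1 1
M7b                protonated_intermediate  -30.0    1 1 -1 1
M9b                protonated_intermediate  -35.0    1 1 -2 1
Int2_beta          monoacetal               -65.0    1 1 -1 0
RO2_beta           open_intermediate       -5.0      1 1 -2 1
")

# ---- named steps: from, to, g_a (NA = equilibrated, no computed TS), tags --
st_tab <- read.table(header = TRUE, text = "
from               to          g_a    ts_id  tags
alpha_xylopyranose 6a          0      NA     1
6a                 8a          37.6   TS_1b  1
8a                 M5a         24.1   TS_1c  1
M5a                Int3_alpha  59.8   TS_1d  1
Int3_alpha         RO3_alpha   NA     NA     1
RO3_alpha          M17a        NA     NA     1
M17a               Int4_alpha  153.4  TS_1e  1
alpha_xylopyranose beta_xylopyranose NA NA   2,3
beta_xylopyranose  beta_xylofuranose 127.5 TS_2b 2,3
beta_xylofuranose  alpha_xylofuranose NA NA  2
alpha_xylofuranose 16a         0      NA     2
16a                18a         1      TS_2e  2
18a                M11a        54     TS_2f  2
M11a               Int4_alpha  102.3  TS_2g  2
beta_xylofuranose  13b         0      NA     3
13b                14b         2      TS_3d  3
14b                M8b         50     TS_3e  3
M8b                Int5_beta   100    TS_3f  3
Int5_beta          Int5_alpha  NA     NA     3
beta_xylofuranose  16b         0      NA     side
16b                17b         5      NA     side
17b                M12b        40     NA     side
M12b               Int4_beta   186.2  NA     side
beta_xylopyranose  6b          0      NA     side
6b                 8b          38     NA     side
8b                 M5b         25     NA     side
M5b                Int3_beta   75     NA     side
Int3_beta          RO3_beta    NA     NA     side
RO3_beta           M16b        NA     NA     side
M16b               Int4_beta   160    NA     side
Int4_alpha         25a         0      NA     1,2
25a                26a         83     TS_1f  1,2
26a                M15a        29.2   TS_1g  1,2
M15a               DFX         81.1   NA     1,2
Int5_alpha         23a         0      NA     3
23a                24a         10     NA     3
24a                M14a        59.8   TS_3h  3
M14a               DFX         70     NA     3
25a                Int6a       60     NA     side
alpha_xylopyranose M1a         0      NA     side
M1a                M2a         40     NA     side
M2a                M3a         55     NA     side
M3a                Int1_alpha  65     NA     side
Int1_alpha         RO1_alpha   NA     NA     side
alpha_xylopyranose M6a         0      NA     side
M6a                M7a         42     NA     side
M7a                M9a         52     NA     side
M9a                Int2_alpha  68     NA     side
Int2_alpha         RO2_alpha   NA     NA     side
beta_xylopyranose  M1b         0      NA     side
M1b                M2b         40     NA     side
M2b                M3b         52     NA     side
M3b                Int1_beta   70     NA     side
Int1_beta          RO1_beta    NA     NA     side
beta_xylopyranose  M6b         0      NA     side
M6b                M7b         41     NA     side
M7b                M9b         48     NA     side
M9b                Int2_beta   80     NA     side
Int2_beta          RO2_beta    NA     NA     side
alpha_xylopyranose RO_apyr     95     NA     side
RO_apyr            open_xylose 60     NA     side
beta_xylopyranose  RO_bpyr     90     NA     side
RO_bpyr            open_xylose 55     NA     side
alpha_xylofuranose RO_afur     98     NA     side
RO_afur            open_xylose 50     NA     side
beta_xylofuranose  RO_bfur     92     NA     side
RO_bfur            open_xylose 48     NA     side
alpha_xylopyranose alpha_xylofuranose 160 NA side
", na.strings = "NA")

# ---- synthetic filler: formylation chemistry considered at the remaining
# hydroxyl positions and on already-formed monoacetals (dead-end branches) ---
set.seed(20251229)
sp_extra <- list(); st_extra <- list()
add_sp <- function(id, role, G, a, b, c, d)
  sp_extra[[length(sp_extra) + 1]] <<- data.frame(id = id, role = role, G = G,
                                                  a = a, b = b, c = c, d = d)
add_st <- function(from, to, g_a, tags = "side")
  st_extra[[length(st_extra) + 1]] <<- data.frame(from = from, to = to, g_a = g_a,
                                                  ts_id = NA, tags = tags)

forms <- c(alpha_xylopyranose = 0, beta_xylopyranose = 10.6,
           alpha_xylofuranose = 9.7, beta_xylofuranose = 17.4)
short <- c(alpha_xylopyranose = "ap", beta_xylopyranose = "bp",
           alpha_xylofuranose = "af", beta_xylofuranose = "bf")
g_of <- function(id) {
  i <- which(sp_tab$id == id)
  if (length(i)) sp_tab$G[i] else {
    hit <- Filter(function(x) x$id == id, sp_extra)
    hit[[length(hit)]]$G
  }
}

for (f in names(forms)) {
  base <- forms[[f]]
  for (p in 1:3) {
    pre <- sprintf("C%s%d", short[[f]], p)
    g1 <- base - runif(1, 10, 40)              # protonated hemiacetal (shallow)
    g2 <- g1 + runif(1, -10, 25)               # after proton transfer
    g3 <- g2 + runif(1, 0, 25)                 # dehydrated cation
    g4 <- base + runif(1, 10, 40)              # strained acetal, not observed
    add_sp(paste0(pre, "_h"), "protonated_intermediate", g1, 1, 1, -1, 1)
    add_sp(paste0(pre, "_p"), "protonated_intermediate", g2, 1, 1, -1, 1)
    add_sp(paste0(pre, "_c"), "protonated_intermediate", g3, 1, 1, -2, 1)
    add_sp(paste0(pre, "_x"), "monoacetal",              g4, 1, 1, -1, 0)
    add_st(f, paste0(pre, "_h"), max(0, g1 - base) + runif(1, 5, 30))
    add_st(paste0(pre, "_h"), paste0(pre, "_p"), max(0, g2 - g1) + runif(1, 1, 15))
    add_st(paste0(pre, "_p"), paste0(pre, "_c"), max(0, g3 - g2) + runif(1, 20, 50))
    add_st(paste0(pre, "_c"), paste0(pre, "_x"), max(0, g4 - g3) + runif(1, 10, 40))
  }
}

# second formylation considered on monoacetals that do not lead to DFX
for (m in c("Int1_alpha", "Int2_alpha", "Int1_beta", "Int2_beta",
            "Int4_beta", "Int5_beta")) {
  base <- g_of(m)
  pre <- paste0("F", m)
  g1 <- base - runif(1, 10, 40)
  g2 <- g1 + runif(1, -10, 25)
  g3 <- g2 + runif(1, 10, 30)
  add_sp(paste0(pre, "_h"), "protonated_intermediate", g1, 1, 2, -2, 1)
  add_sp(paste0(pre, "_p"), "protonated_intermediate", g2, 1, 2, -2, 1)
  add_sp(paste0(pre, "_c"), "protonated_intermediate", g3, 1, 2, -3, 1)
  add_st(m, paste0(pre, "_h"), max(0, g1 - base) + runif(1, 5, 25))
  add_st(paste0(pre, "_h"), paste0(pre, "_p"), max(0, g2 - g1) + runif(1, 2, 20))
  add_st(paste0(pre, "_p"), paste0(pre, "_c"), max(0, g3 - g2) + runif(1, 30, 60))
}

# formylation considered on the ring-opened sugar cations (dead ends)
for (r in c("RO_apyr", "RO_bpyr", "RO_afur", "RO_bfur")) {
  base <- g_of(r)
  pre <- paste0("F", r)
  g1 <- base - runif(1, 10, 35)
  g2 <- g1 + runif(1, 0, 20)
  add_sp(paste0(pre, "_h"), "protonated_intermediate", g1, 1, 1, -2, 1)
  add_sp(paste0(pre, "_p"), "protonated_intermediate", g2, 1, 1, -2, 1)
  add_st(r, paste0(pre, "_h"), max(0, g1 - base) + runif(1, 5, 25))
  add_st(paste0(pre, "_h"), paste0(pre, "_p"), max(0, g2 - g1) + runif(1, 2, 20))
}

sp_tab <- rbind(sp_tab, do.call(rbind, sp_extra))
st_tab <- rbind(st_tab, do.call(rbind, st_extra))
stopifnot(!anyDuplicated(sp_tab$id), nrow(st_tab) >= 140)

# ---- energy terms reproducing the potentials via Eq-3-style referencing ----
ref_terms <- list(
  alpha_xylopyranose = list(E = -1995000, ZPE = 420, S = 430),
  HCHO = list(E = -300000, ZPE = 70, S = 220),
  H2O = list(E = -200600, ZPE = 55, S = 190),
  `H3O+` = list(E = -201500, ZPE = 90, S = 200)
)
gref <- vapply(ref_terms, function(x) x$E + x$ZPE - T0 * x$S / 1000, numeric(1))

make_species <- function(row) {
  id <- row$id
  stoich <- c(row$a, row$b, row$c, row$d)
  if (id %in% names(ref_terms)) {
    et <- ref_terms[[id]]
  } else {
    zpe <- 420 * row$a + 70 * row$b + 55 * row$c + 90 * row$d + 5
    s <- 430 * row$a + 220 * row$b + 190 * row$c + 200 * row$d - 40
    e <- row$G + sum(stoich * gref) - zpe + T0 * s / 1000
    et <- list(E = e, ZPE = zpe, S = s)
  }
  species(id, row$role, charge = as.integer(row$d), stoich = stoich,
          energy_terms = et, g_formation = row$G,
          note = if (id == "M17a") "alias M4b" else NA_character_)
}
sp_list <- lapply(seq_len(nrow(sp_tab)), function(i) make_species(sp_tab[i, ]))

make_step <- function(row, k) {
  gf <- g_of(row$from); gt <- g_of(row$to)
  sf <- sp_tab[sp_tab$id == row$from, ]; st <- sp_tab[sp_tab$id == row$to, ]
  diff <- c(HCHO = st$b - sf$b, H2O = st$c - sf$c, `H3O+` = st$d - sf$d)
  names(diff) <- c("HCHO", "H2O", "H3O+")
  consumes <- diff[diff > 0]; releases <- -diff[diff < 0]
  elementary_step(sprintf("s%03d", k), row$from, row$to,
                  delta_g = gt - gf, g_a = row$g_a,
                  ts_id = if (is.na(row$ts_id)) NA_character_ else row$ts_id,
                  consumes = consumes, releases = releases,
                  reversible = TRUE, equilibrated = is.na(row$g_a),
                  tags = strsplit(as.character(row$tags), ",")[[1]])
}
st_list <- lapply(seq_len(nrow(st_tab)), function(i) make_step(st_tab[i, ], i))

net <- reaction_network(sp_list, st_list,
                        references = c("alpha_xylopyranose", "HCHO", "H2O", "H3O+"),
                        temperature = T0)
v <- validate_network(net)
stopifnot(nrow(v) == 0)
g_et <- formation_free_energies(net)
stopifnot(max(abs(g_et - sp_tab$G[match(names(g_et), sp_tab$id)])) < 1e-6)

save_network(net, "inst/extdata/xylose_fa_network_synthetic.json")

# small pathway-2 fixture: the beta-anomerization route to Int4_alpha
p2_states <- c("alpha_xylopyranose", "HCHO", "H2O", "H3O+",
               "beta_xylopyranose", "beta_xylofuranose", "alpha_xylofuranose",
               "16a", "18a", "M11a", "Int4_alpha")
p2_steps <- Filter(function(s) s$from %in% p2_states && s$to %in% p2_states &&
                     "2" %in% s$tags, net$steps)
p2 <- reaction_network(net$species[p2_states], p2_steps,
                       references = net$references, temperature = T0)
stopifnot(nrow(validate_network(p2)) == 0)
save_network(p2, "inst/extdata/pathway2.json")

# ---- synthetic aldehyde descriptor table (Table-S4-like shape) -------------
ald <- data.frame(
  name = c("FA", "PA", "DA", "BnA", "FBnA"),
  ei_cho_target = c(38, 30.5, 26.5, 19.5, 23.5),   # kcal/mol, straddling 28-29
  spin_density_C = c(0.72, 0.62, 0.60, 0.42, 0.45),
  eta_ev = c(3.60, 3.50, 3.45, 2.90, 2.85),
  q_neutral = c(0.121, 0.146, 0.150, 0.132, 0.158)
)
ei_ev <- convert_energy(ald$ei_cho_target / ald$spin_density_C, "kcal/mol", "eV")
mu <- -sqrt(2 * ald$eta_ev * ei_ev)
fukui <- c(0.302, 0.251, 0.243, 0.172, 0.196)
desc <- data.frame(name = ald$name,
                   e_homo = round(mu - ald$eta_ev, 6),
                   e_lumo = round(mu + ald$eta_ev, 6),
                   unit = "eV",
                   spin_density_C = ald$spin_density_C,
                   q_neutral = ald$q_neutral,
                   q_radical = ald$q_neutral + fukui)
con <- file("inst/extdata/aldehyde_descriptors_synthetic.csv", "w")
writeLines("# synthetic descriptor table: values constructed, not computed from wavefunctions", con)
write.csv(desc, con, row.names = FALSE, quote = FALSE)
close(con)

cat("species:", length(net$species), " steps:", length(net$steps), "\n")
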