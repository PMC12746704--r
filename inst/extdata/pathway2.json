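{"schema_version":"1.0","units":"kJ/mol","temperature_K":333.15,"references":["alpha_xylopyranose","HCHO","H2O","H3O+"],"species":[{"id":"alpha_xylopyranose","role":"sugar_tautomer","charge":0,"stoich":[1,0,0,0],"energy_terms":{"E":-1995000,"ZPE":420,"S":430},"g_formation":0},{"id":"HCHO","role":"reference","charge":0,"stoich":[0,1,0,0],"energy_terms":{"E":-300000,"ZPE":70,"S":220},"g_formation":0},{"id":"H2O","role":"reference","charge":0,"stoich":[0,0,1,0],"energy_terms":{"E":-200600,"ZPE":55,"S":190},"g_formation":0},{"id":"H3O+","role":"reference","charge":1,"stoich":[0,0,0,1],"energy_terms":{"E":-201500,"ZPE":90,"S":200},"g_formation":0},{"id":"beta_xylopyranose","role":"sugar_tautomer","charge":0,"stoich":[1,0,0,0],"energy_terms":{"E":-1995007.726,"ZPE":425,"S":390},"g_formation":10.6},{"id":"beta_xylofuranose","role":"sugar_tautomer","charge":0,"stoich":[1,0,0,0],"energy_terms":{"E":-1995000.926,"ZPE":425,"S":390},"g_formation":17.4},{"id":"alpha_xylofuranose","role":"sugar_tautomer","charge":0,"stoich":[1,0,0,0],"energy_terms":{"E":-1995008.626,"ZPE":425,"S":390},"g_formation":9.7},{"id":"16a","role":"protonated_intermediate","charge":1,"stoich":[1,1,-1,1],"energy_terms":{"E":-2296097.726,"ZPE":530,"S":620},"g_formation":-179.4},{"id":"18a","role":"protonated_intermediate","charge":1,"stoich":[1,1,-1,1],"energy_terms":{"E":-2296102.726,"ZPE":530,"S":620},"g_formation":-184.4},{"id":"M11a","role":"protonated_intermediate","charge":1,"stoich":[1,1,-2,1],"energy_terms":{"E":-2095452.526,"ZPE":475,"S":430},"g_formation":-134.2},{"id":"Int4_alpha","role":"monoacetal","charge":0,"stoich":[1,1,-1,0],"energy_terms":{"E":-2094496.526,"ZPE":440,"S":420},"g_formation":-78.2}],"steps":[{"id":"s008","from":"alpha_xylopyranose","to":"beta_xylopyranose","delta_g":10.6,"g_a":null,"ts_id":null,"consumes":{},"releases":{},"reversible":true,"equilibrated":true,"tags":["2","3"]},{"id":"s009","from":"beta_xylopyranose","to":"beta_xylofuranose","delta_g":6.8,"g_a":127.5,"ts_id":"TS_2b","consumes":{},"releases":{},"reversible":true,"equilibrated":false,"tags":["2","3"]},{"id":"s010","from":"beta_xylofuranose","to":"alpha_xylofuranose","delta_g":-7.7,"g_a":null,"ts_id":null,"consumes":{},"releases":{},"reversible":true,"equilibrated":true,"tags":["2"]},{"id":"s011","from":"alpha_xylofuranose","to":"16a","delta_g":-189.1,"g_a":0,"ts_id":null,"consumes":{"HCHO":1,"H3O+":1},"releases":{"H2O":1},"reversible":true,"equilibrated":false,"tags":["2"]},{"id":"s012","from":"16a","to":"18a","delta_g":-5,"g_a":1,"ts_id":"TS_2e","consumes":{},"releases":{},"reversible":true,"equilibrated":false,"tags":["2"]},{"id":"s013","from":"18a","to":"M11a","delta_g":50.2,"g_a":54,"ts_id":"TS_2f","consumes":{},"releases":{"H2O":1},"reversible":true,"equilibrated":false,"tags":["2"]},{"id":"s014","from":"M11a","to":"Int4_alpha","delta_g":56,"g_a":102.3,"ts_id":"TS_2g","consumes":{"H2O":1},"releases":{"H3O+":1},"reversible":true,"equilibrated":false,"tags":["2"]}]}
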