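# Composition sheet of the studied thermally conditioned sewage sludge
# (total P from the text value that reproduces the equivalent-rate column).
name: TCSS
total_p_g_per_kg: 23.30
dry_solid_pct: 57
constituents:
  organic_C: {value: 214, unit: g_per_kg}
  total_N: {value: 13, unit: g_per_kg}
  N_NO3: {value: 0.03, unit: mg_per_kg}
  N_NH4: {value: 1.9, unit: g_per_kg}
  Olsen_P: {value: 0.24, unit: g_per_kg}
  organic_P: {value: 0.8, unit: g_per_kg}
  total_K: {value: 1.4, unit: g_per_kg}
  Al: {value: 29.6, unit: g_per_kg}
  Fe: {value: 11.5, unit: g_per_kg}
  CaCO3: {value: 217, unit: g_per_kg}
  Mn: {value: 297, unit: mg_per_kg}
  Cu: {value: 731, unit: mg_per_kg}
  Zn: {value: 2408, unit: mg_per_kg}
  Cr: {value: 134, unit: mg_per_kg}
  Ni: {value: 57, unit: mg_per_kg}
  Pb: {value: 463, unit: mg_per_kg}
  Cd: {value: 15, unit: mg_per_kg}
  Hg: {value: 7, unit: mg_per_kg}
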