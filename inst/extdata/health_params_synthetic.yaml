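# SYNTHETIC health-model parameter set for an OFS wheat assessment at the
# scale of a North-China wheat province. The demographic inputs such an
# assessment needs (wheat consumption, baseline intakes, RNIs, baseline
# DALY burdens, PCNI) are not measured data here; this file is a
# back-solved, internally consistent stand-in built around the reference
# scenario table the package targets:
#
#   * baseline_intake values are the status-quo daily intakes of that
#     scenario table;
#   * rni values are back-solved from its (intake-with-OFS, %RNI) pairs,
#     e.g. Zn infants 4.96 / 0.7188 = 6.90 mg/day;
#   * wheat_intake and the grain-content deltas are chosen jointly so that
#     delta * intake/1000 * recovery reproduces its additional intakes
#     (e.g. Zn infants: 1.94 mg/kg * 0.100 kg/day * 0.310
#     = 0.060 mg/day -> 4.90 + 0.06 = 4.96);
#   * baseline_burden values are back-solved from its 15%-substitution
#     pessimistic DALYs-saved column under the linear gap-closure model,
#     burden = saved / (coverage * gap), e.g. Zn infants:
#     771 / (0.20 * 0.0601/2.00) = 128201 DALYs;
#   * pcni is back-solved from the corresponding pessimistic economic
#     cell: (8.0e8 + 900 * 4.0e6) / 91340 = 48172 RMB per DALY;
#   * populations are plausible provincial magnitudes and are descriptive
#     only (burdens are given directly).
#
# Units: wheat_intake g/day; baseline_intake, rni mg/day; contents mg/kg;
# baseline_burden DALYs/year; pcni RMB/DALY; fertilizer_cost_per_ha
# RMB/ha; area_ha ha.

reference_treatment: OPT

recovery:
  Zn: 0.310
  Fe: 0.217

contents:            # grain mineral content by treatment, mg/kg (synthetic)
  Zn: {OPT: 23.90, OF15: 25.84, OF30: 26.00}
  Fe: {OPT: 37.00, OF15: 40.00, OF30: 39.19}

groups:
  - {nutrient: Zn, group: Infants,            population: 6000000,
     wheat_intake: 100, baseline_intake: 4.90,  rni: 6.90,
     baseline_burden: 128201}
  - {nutrient: Zn, group: Children,           population: 12000000,
     wheat_intake: 200, baseline_intake: 6.00,  rni: 8.00,
     baseline_burden: 436815}
  - {nutrient: Fe, group: Children <5 years,  population: 6000000,
     wheat_intake: 200, baseline_intake: 11.90, rni: 14.30,
     baseline_burden: 941106}
  - {nutrient: Fe, group: Children 6-14 years, population: 12000000,
     wheat_intake: 200, baseline_intake: 18.70, rni: 23.50,
     baseline_burden: 2944700}
  - {nutrient: Fe, group: Men 15+,            population: 40000000,
     wheat_intake: 400, baseline_intake: 24.40, rni: 27.40,
     baseline_burden: 2840092}
  - {nutrient: Fe, group: Women 15+,          population: 40000000,
     wheat_intake: 400, baseline_intake: 21.20, rni: 58.80,
     baseline_burden: 7061551}
  - {nutrient: Fe, group: Pregnant women,     population: 1000000,
     wheat_intake: 400, baseline_intake: 21.20, rni: 58.80,
     baseline_burden: 31767}

scenarios:
  - {name: pessimistic, coverage: 0.20}
  - {name: optimistic,  coverage: 0.60}

economics:
  pcni: 48172
  fertilizer_cost_per_ha: 900
  area_ha: 4000000
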