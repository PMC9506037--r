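{
  "units": {
    "a0": "L^2 bar / mol^2",
    "b": "L / mol",
    "c1": "dimensionless",
    "eps_assoc": "bar L / mol",
    "beta_assoc": "dimensionless",
    "tc": "K",
    "mw": "g / mol",
    "kij": "dimensionless"
  },
  "components": [
    {"name": "CO2",                  "mw": 44.01,  "tc": 304.2, "a0": 3.5079,  "b": 0.0272, "c1": 0.7602, "eps_assoc": 0,      "beta_assoc": 0,      "scheme": "none"},
    {"name": "methanol",             "mw": 32.04,  "tc": 512.6, "a0": 4.0531,  "b": 0.0310, "c1": 0.4310, "eps_assoc": 245.91, "beta_assoc": 0.0161, "scheme": "2B"},
    {"name": "ethanol",              "mw": 46.07,  "tc": 513.9, "a0": 8.6716,  "b": 0.0491, "c1": 0.7369, "eps_assoc": 215.32, "beta_assoc": 0.0080, "scheme": "2B"},
    {"name": "glycerol",             "mw": 92.09,  "tc": 850.0, "a0": 11.80,   "b": 0.0696, "c1": 0.90,   "eps_assoc": 207.85, "beta_assoc": 0.0133, "scheme": "3x2B"},
    {"name": "ethylene_glycol",      "mw": 62.07,  "tc": 720.0, "a0": 13.259,  "b": 0.0521, "c1": 0.9245, "eps_assoc": 143.37, "beta_assoc": 0.0188, "scheme": "4C"},
    {"name": "diethylene_glycol",    "mw": 106.12, "tc": 744.6, "a0": 24.029,  "b": 0.0922, "c1": 1.2409, "eps_assoc": 143.37, "beta_assoc": 0.0188, "scheme": "4C"},
    {"name": "triethylene_glycol",   "mw": 150.17, "tc": 769.5, "a0": 38.485,  "b": 0.1323, "c1": 1.2254, "eps_assoc": 143.37, "beta_assoc": 0.0188, "scheme": "4C"},
    {"name": "tetraethylene_glycol", "mw": 194.23, "tc": 795.0, "a0": 53.936,  "b": 0.1751, "c1": 1.4228, "eps_assoc": 143.37, "beta_assoc": 0.0188, "scheme": "4C"},
    {"name": "lauric_acid",          "mw": 200.32, "tc": 743.0, "a0": 72.958,  "b": 0.2270, "c1": 1.6113, "eps_assoc": 236.08, "beta_assoc": 7.75e-4, "scheme": "1A"},
    {"name": "methyl_palmitate",     "mw": 270.45, "tc": 762.2, "a0": 105.049, "b": 0.3155, "c1": 1.5496, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "methyl_stearate",      "mw": 298.50, "tc": 781.1, "a0": 122.585, "b": 0.3518, "c1": 1.5966, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "methyl_oleate",        "mw": 296.49, "tc": 764.0, "a0": 115.416, "b": 0.3324, "c1": 1.6709, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "methyl_linoleate",     "mw": 294.47, "tc": 795.3, "a0": 105.250, "b": 0.3189, "c1": 1.7639, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "methyl_linolenate",    "mw": 292.46, "tc": 797.2, "a0": 105.310, "b": 0.3117, "c1": 1.7642, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "tributyrin",           "mw": 302.36, "tc": 658.7, "a0": 135.39,  "b": 0.3005, "c1": 1.0563, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "tricaprylin",          "mw": 470.68, "tc": 793.4, "a0": 239.40,  "b": 0.5202, "c1": 1.5765, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "trilaurin",            "mw": 639.00, "tc": 869.8, "a0": 369.12,  "b": 0.7400, "c1": 1.8191, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "trimyristin",          "mw": 723.16, "tc": 898.6, "a0": 444.95,  "b": 0.8498, "c1": 1.9035, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "triolein",             "mw": 885.43, "tc": 977.9, "a0": 555.89,  "b": 1.0506, "c1": 2.1070, "eps_assoc": 0, "beta_assoc": 0, "scheme": "none"},
    {"name": "PEG150", "mw": 150, "tc": 766,  "a0": 39.197,  "a0_poly": 38.023,  "b": 0.1332, "c1": 1.2993, "eps_assoc": 143.37, "beta_assoc": 0.0188, "scheme": "4C"},
    {"name": "PEG200", "mw": 200, "tc": 812,  "a0": 54.688,  "a0_poly": 56.337,  "b": 0.1797, "c1": 1.4135, "eps_assoc": 143.37, "beta_assoc": 0.0188, "scheme": "4C"},
    {"name": "PEG300", "mw": 300, "tc": 961,  "a0": 85.670,  "a0_poly": 102.004, "b": 0.2726, "c1": 1.5744, "eps_assoc": 143.37, "beta_assoc": 0.0188, "scheme": "4C"},
    {"name": "PEG400", "mw": 400, "tc": 1186, "a0": 116.652, "a0_poly": 159.723, "b": 0.3654, "c1": 1.6885, "eps_assoc": 143.37, "beta_assoc": 0.0188, "scheme": "4C"},
    {"name": "PEG600", "mw": 600, "tc": 1860, "a0": 178.616, "a0_poly": 311.315, "b": 0.5512, "c1": 1.8494, "eps_assoc": 143.37, "beta_assoc": 0.0188, "scheme": "4C"}
  ],
  "synonyms": {
    "carbon_dioxide": "CO2",
    "co2": "CO2",
    "meg": "ethylene_glycol",
    "deg": "diethylene_glycol",
    "teg": "triethylene_glycol",
    "tetraeg": "tetraethylene_glycol",
    "glycerine": "glycerol",
    "peg_150": "PEG150",
    "peg_200": "PEG200",
    "peg_300": "PEG300",
    "peg_400": "PEG400",
    "peg_600": "PEG600"
  },
  "binaries": [
    {"i": "CO2", "j": "PEG150", "kij": 0.0420,  "cross_rule": "none"},
    {"i": "CO2", "j": "PEG200", "kij": 0.0195,  "cross_rule": "none"},
    {"i": "CO2", "j": "PEG300", "kij": -0.0200, "cross_rule": "none"},
    {"i": "CO2", "j": "PEG400", "kij": -0.0617, "cross_rule": "none"},
    {"i": "CO2", "j": "glycerol", "variant": "inert",    "kij": 0.1643, "cross_rule": "none"},
    {"i": "CO2", "j": "glycerol", "variant": "one-site", "kij": 0.3084, "cross_rule": "mCR1", "beta_cross": 0.0979, "default": true},
    {"i": "CO2", "j": "tricaprylin", "kij": 0.0522,  "cross_rule": "none"},
    {"i": "CO2", "j": "tributyrin",  "kij": -0.0165, "cross_rule": "none"},
    {"i": "CO2", "j": "trilaurin",   "kij": 0.0708,  "cross_rule": "none"},
    {"i": "CO2", "j": "trimyristin", "kij": 0.0905,  "cross_rule": "none"},
    {"i": "CO2", "j": "triolein",    "kij": 0.0585,  "cross_rule": "none"},
    {"i": "CO2", "j": "methanol", "kij": 0.0479, "cross_rule": "explicit", "eps_cross": 123.8, "beta_cross": 0.0196},
    {"i": "CO2", "j": "ethanol",  "kij": 0.1132, "cross_rule": "explicit", "eps_cross": 123.8, "beta_cross": 0.0320},
    {"i": "CO2", "j": "lauric_acid",       "kij": 0.0380, "cross_rule": "none"},
    {"i": "CO2", "j": "methyl_linoleate",  "kij": 0.0480, "cross_rule": "none"},
    {"i": "CO2", "j": "methyl_oleate",     "kij": 0.0566, "cross_rule": "none"},
    {"i": "CO2", "j": "methyl_linolenate", "kij": 0.3000, "cross_rule": "none"},
    {"i": "CO2", "j": "methyl_palmitate",  "kij": 0.0653, "cross_rule": "none"},
    {"i": "CO2", "j": "methyl_stearate",   "kij": 0.0715, "cross_rule": "none"},
    {"i": "glycerol", "j": "methanol", "kij": 0.0836, "cross_rule": "CR1"},
    {"i": "glycerol", "j": "ethanol",  "kij": 0.0226, "cross_rule": "CR1"},
    {"i": "lauric_acid", "j": "methanol", "kij": -0.0181, "cross_rule": "mCR1", "beta_cross": 0.1028},
    {"i": "methyl_palmitate", "j": "methyl_stearate",   "kij": 0, "cross_rule": "none"},
    {"i": "methyl_palmitate", "j": "methyl_oleate",     "kij": 0, "cross_rule": "none"},
    {"i": "methyl_palmitate", "j": "methyl_linoleate",  "kij": 0, "cross_rule": "none"},
    {"i": "methyl_palmitate", "j": "methyl_linolenate", "kij": 0, "cross_rule": "none"},
    {"i": "methyl_stearate",  "j": "methyl_oleate",     "kij": 0, "cross_rule": "none"},
    {"i": "methyl_stearate",  "j": "methyl_linoleate",  "kij": 0, "cross_rule": "none"},
    {"i": "methyl_stearate",  "j": "methyl_linolenate", "kij": 0, "cross_rule": "none"},
    {"i": "methyl_oleate",    "j": "methyl_linoleate",  "kij": 0, "cross_rule": "none"},
    {"i": "methyl_oleate",    "j": "methyl_linolenate", "kij": 0, "cross_rule": "none"},
    {"i": "methyl_linoleate", "j": "methyl_linolenate", "kij": 0, "cross_rule": "none"}
  ]
}
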