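{
  "converged": true,
  "table": [
    {
      "setting": "rural",
      "target": "age18_total_myopia_pct.SCHOOL_SCREENING",
      "printed": 89.16,
      "model": 89.16,
      "deviation": 0,
      "tolerance": 0.05,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "age18_total_myopia_pct.TRADITIONAL",
      "printed": 87.63,
      "model": 87.63,
      "deviation": 0,
      "tolerance": 0.05,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "age18_total_myopia_pct.DIGITAL",
      "printed": 85.37,
      "model": 85.37,
      "deviation": 0,
      "tolerance": 0.05,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "high_myopia_reduction_pp",
      "printed": 1.81,
      "model": 1.81017844973972,
      "deviation": 0.000178449739724362,
      "tolerance": 0.05,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "cost_per_person.SCHOOL_SCREENING",
      "printed": 171,
      "model": 170.998930197739,
      "deviation": -6.25615357185322e-06,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "qaly_per_person.SCHOOL_SCREENING",
      "printed": 9.57764,
      "model": 9.57562234203935,
      "deviation": -0.000210663374344144,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "daly_per_person.SCHOOL_SCREENING",
      "printed": 0.06562,
      "model": 0.0653241096825589,
      "deviation": -0.00450914839136078,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "cost_per_person.TRADITIONAL",
      "printed": 218,
      "model": 218.020021450161,
      "deviation": 9.18415144988749e-05,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "qaly_per_person.TRADITIONAL",
      "printed": 9.58509,
      "model": 9.5849649808446,
      "deviation": -1.30430862309501e-05,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "daly_per_person.TRADITIONAL",
      "printed": 0.06189,
      "model": 0.0620575440370363,
      "deviation": 0.00270712614374301,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "cost_per_person.DIGITAL",
      "printed": 324,
      "model": 323.848901150001,
      "deviation": -0.000466354475307009,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "qaly_per_person.DIGITAL",
      "printed": 9.59448,
      "model": 9.59651579670962,
      "deviation": 0.000212184163145367,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "daly_per_person.DIGITAL",
      "printed": 0.05905,
      "model": 0.0591564792274509,
      "deviation": 0.00180320452922821,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "rural",
      "target": "cost_per_person.PERFECT_OUTDOOR",
      "printed": 321,
      "model": 321.114136977797,
      "deviation": 0.000355566909024886,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "age18_total_myopia_pct.SCHOOL_SCREENING",
      "printed": 90.04,
      "model": 90.04,
      "deviation": 0,
      "tolerance": 0.05,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "age18_total_myopia_pct.TRADITIONAL",
      "printed": 88.64,
      "model": 88.64,
      "deviation": 0,
      "tolerance": 0.05,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "age18_total_myopia_pct.DIGITAL",
      "printed": 86.56,
      "model": 86.56,
      "deviation": 1.4210854715202e-14,
      "tolerance": 0.05,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "high_myopia_reduction_pp",
      "printed": 1.35,
      "model": 1.34999727061426,
      "deviation": -2.72938574408244e-06,
      "tolerance": 0.05,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "cost_per_person.SCHOOL_SCREENING",
      "printed": 607,
      "model": 606.886186274086,
      "deviation": -0.000187502019627747,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "qaly_per_person.SCHOOL_SCREENING",
      "printed": 9.56321,
      "model": 9.56168520844616,
      "deviation": -0.000159443487473081,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "daly_per_person.SCHOOL_SCREENING",
      "printed": 0.06552,
      "model": 0.0650383380705485,
      "deviation": -0.00735137254962559,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "cost_per_person.TRADITIONAL",
      "printed": 729,
      "model": 729.31136323748,
      "deviation": 0.000427110065130328,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "qaly_per_person.TRADITIONAL",
      "printed": 9.57119,
      "model": 9.57101688581735,
      "deviation": -1.80870072212297e-05,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "daly_per_person.TRADITIONAL",
      "printed": 0.05886,
      "model": 0.0592147149719264,
      "deviation": 0.0060264181434997,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "cost_per_person.DIGITAL",
      "printed": 819,
      "model": 815.758479209058,
      "deviation": -0.00395790084364088,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "qaly_per_person.DIGITAL",
      "printed": 9.57964,
      "model": 9.58125356404846,
      "deviation": 0.000168436814792463,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "daly_per_person.DIGITAL",
      "printed": 0.0567,
      "model": 0.0567724707471444,
      "deviation": 0.00127814368861461,
      "tolerance": 0.01,
      "pass": true
    },
    {
      "setting": "urban",
      "target": "cost_per_person.PERFECT_OUTDOOR",
      "printed": 808,
      "model": 811.053399648525,
      "deviation": 0.0037789599610462,
      "tolerance": 0.01,
      "pass": true
    }
  ],
  "notes": "Utilities, disability weights and unit costs are fitted per setting; multiple parameter sets reproduce the anchors equally well (documented degeneracy). Subgroup DALY/ICER values other than the perfect-outdoor cost are not calibration constraints."
}
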