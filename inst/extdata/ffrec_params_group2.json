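{
  "version": "2.0",
  "group": 2,
  "note": "Synthetic ground-truth pack, amplification-dominated columns: L2/3 recurrent weights increase with SF. dt values are log-ms. Weights are DC transfer amplitudes under net-area kernel normalization.",
  "sf": [0.625, 1.25, 2.5, 5, 7.5, 10, 15],
  "layers": {
    "L2": {
      "w_m": 0.2991,
      "w_p": 0.2859,
      "dt_m1": 2.70805020110221,
      "sigma_m1": 0.4,
      "dt_m2": 3.68887945411394,
      "sigma_m2": 0.3,
      "g_m": 0.25,
      "dt_p1": 2.89037175789616,
      "sigma_p1": 0.45,
      "dt_p2": 3.80666248977032,
      "sigma_p2": 0.3,
      "g_p": 0.2,
      "dt_rec": 4.17438726989564,
      "sigma_rec": 0.35,
      "w_rec": {
        "0.625": 0,
        "1.25": 0,
        "2.5": 0.57,
        "5": 3.812,
        "7.5": 15.769,
        "10": 16.836,
        "15": 14.437
      }
    },
    "L3": {
      "w_m": 0.3072,
      "w_p": 0.3057,
      "dt_m1": 2.70805020110221,
      "sigma_m1": 0.4,
      "dt_m2": 3.68887945411394,
      "sigma_m2": 0.3,
      "g_m": 0.25,
      "dt_p1": 2.89037175789616,
      "sigma_p1": 0.45,
      "dt_p2": 3.80666248977032,
      "sigma_p2": 0.3,
      "g_p": 0.2,
      "dt_rec": 4.17438726989564,
      "sigma_rec": 0.35,
      "w_rec": {
        "0.625": 0,
        "1.25": 0,
        "2.5": 0.57,
        "5": 3.24,
        "7.5": 14.017,
        "10": 14.54,
        "15": 12.771
      }
    },
    "L4B": {
      "w_m": 0.3435,
      "w_p": 0.2707,
      "dt_m1": 2.63905732961526,
      "sigma_m1": 0.38,
      "dt_m2": 3.63758615972639,
      "sigma_m2": 0.3,
      "g_m": 0.25,
      "dt_p1": 2.89037175789616,
      "sigma_p1": 0.45,
      "dt_p2": 3.80666248977032,
      "sigma_p2": 0.3,
      "g_p": 0.2,
      "dt_rec": 4.17438726989564,
      "sigma_rec": 0.35,
      "w_rec": {
        "0.625": 0,
        "1.25": 0,
        "2.5": 0,
        "5": 0,
        "7.5": 0,
        "10": 0,
        "15": 0
      }
    },
    "L5": {
      "w_m": 0.2954,
      "w_p": 0.2922,
      "dt_m1": 2.77258872223978,
      "sigma_m1": 0.42,
      "dt_m2": 3.73766961828337,
      "sigma_m2": 0.3,
      "g_m": 0.25,
      "dt_p1": 2.99573227355399,
      "sigma_p1": 0.45,
      "dt_p2": 3.87120101090789,
      "sigma_p2": 0.3,
      "g_p": 0.2,
      "dt_rec": 4.17438726989564,
      "sigma_rec": 0.35,
      "w_rec": {
        "0.625": 0,
        "1.25": 0,
        "2.5": 0,
        "5": 0.762,
        "7.5": 2.103,
        "10": 2.296,
        "15": 1.999
      }
    },
    "L6": {
      "w_m": 0.2474,
      "w_p": 0.2774,
      "dt_m1": 2.77258872223978,
      "sigma_m1": 0.42,
      "dt_m2": 3.73766961828337,
      "sigma_m2": 0.3,
      "g_m": 0.25,
      "dt_p1": 2.99573227355399,
      "sigma_p1": 0.45,
      "dt_p2": 3.87120101090789,
      "sigma_p2": 0.3,
      "g_p": 0.2,
      "dt_rec": 4.17438726989564,
      "sigma_rec": 0.35,
      "w_rec": {
        "0.625": 0,
        "1.25": 0,
        "2.5": 0,
        "5": 0,
        "7.5": 0,
        "10": 0,
        "15": 0
      }
    }
  }
}
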