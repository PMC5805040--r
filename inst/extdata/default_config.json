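{
  "cohort": {
    "deployment_size": {
      "value": 50000,
      "low": 35000,
      "high": 80000,
      "dist": "triangular"
    },
    "duration_months": {
      "value": 3.5,
      "low": 1,
      "high": 12,
      "dist": "triangular"
    },
    "monthly_incidence": {
      "value": 0.28899999999999998,
      "low": 0.16200000000000001,
      "high": 0.41599999999999998,
      "dist": "normal"
    }
  },
  "parameters": {
    "p_no_mh": {
      "value": 0.69069999999999998,
      "low": 0.68000000000000005,
      "high": 0.87,
      "dist": "triangular"
    },
    "p_run_course": {
      "value": 0.59999999999999998,
      "low": 0.29999999999999999,
      "high": 0.90000000000000002,
      "dist": "triangular"
    },
    "p_self_success": {
      "value": 0.32000000000000001,
      "low": 0.16,
      "high": 0.47999999999999998,
      "dist": "triangular"
    },
    "p_self_failure": {
      "value": 0.080000000000000002,
      "low": 0.040000000000000001,
      "high": 0.12,
      "dist": "triangular"
    },
    "p_medevac": {
      "value": 0.00029999999999999997,
      "low": 0.00020000000000000001,
      "high": 0.00040000000000000002,
      "dist": "triangular"
    },
    "p_mh_treatment": {
      "value": 0.29999999999999999,
      "low": 0.13,
      "high": 0.41999999999999998,
      "dist": "triangular"
    },
    "p_suboptimal": {
      "value": 0.27800000000000002,
      "low": 0.16,
      "high": 0.51000000000000001,
      "dist": "triangular"
    },
    "p_optimal": {
      "value": 0.35099999999999998,
      "low": 0.27000000000000002,
      "high": 0.56999999999999995,
      "dist": "triangular"
    },
    "p_bedrest": {
      "value": 0.371,
      "low": 0.13,
      "high": 0.46999999999999997,
      "dist": "triangular"
    },
    "p_hospitalization": {
      "value": 0.0089999999999999993,
      "low": 0.0030000000000000001,
      "high": 0.024,
      "dist": "triangular"
    },
    "cost_medevac": {
      "value": 16938,
      "low": 13550,
      "high": 20326,
      "dist": "triangular"
    },
    "cost_hospital": {
      "value": 2907,
      "low": 2325,
      "high": 3488,
      "dist": "triangular"
    },
    "cost_bedrest": {
      "value": 104,
      "low": 84,
      "high": 125,
      "dist": "triangular"
    },
    "cost_suboptimal": {
      "value": 70,
      "low": 56,
      "high": 84,
      "dist": "triangular"
    },
    "cost_optimal": {
      "value": 82,
      "low": 65,
      "high": 98,
      "dist": "triangular"
    },
    "cost_self_failure": {
      "value": 27,
      "low": 22,
      "high": 32,
      "dist": "triangular"
    },
    "ddl_suboptimal": {
      "value": 0.69999999999999996,
      "low": 0.40000000000000002,
      "high": 1,
      "dist": "normal"
    },
    "ddl_optimal": {
      "value": 0.37,
      "low": 0.23000000000000001,
      "high": 0.52000000000000002,
      "dist": "normal"
    },
    "ddl_bedrest": {
      "value": 1.6000000000000001,
      "low": 1,
      "high": 2,
      "dist": "triangular"
    },
    "ddl_hospital": {
      "value": 1.7,
      "low": 1,
      "high": 3,
      "dist": "triangular"
    },
    "ddl_medevac": {
      "value": 7,
      "low": 3,
      "high": 10,
      "dist": "triangular"
    },
    "ddl_run_course": {
      "value": 0.37,
      "low": 0.23000000000000001,
      "high": 0.52000000000000002,
      "dist": "normal"
    },
    "ddl_self_success": {
      "value": 0.17999999999999999,
      "low": 0.11,
      "high": 0.25,
      "dist": "normal"
    },
    "ddl_self_failure": {
      "value": 0.47999999999999998,
      "low": 0.28999999999999998,
      "high": 0.67000000000000004,
      "dist": "normal"
    }
  }
}
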