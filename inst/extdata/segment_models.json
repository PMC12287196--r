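{
  "provenance": "Packaged segment regression models fitted to 240 harmonized thermal-manikin clothing ensembles (overall insulation 0.22-2.17 clo); thresholded linear / continuous piecewise-linear form max(a*I_cl+b, c).",
  "models": [
    {"segment": "head", "posture": "standing", "kind": "constant", "a1": 0, "b1": 0.13, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.13, "r2": null},
    {"segment": "head", "posture": "sitting", "kind": "constant", "a1": 0, "b1": 0.13, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.13, "r2": null},
    {"segment": "head", "posture": "generic", "kind": "constant", "a1": 0, "b1": 0.13, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.13, "r2": null},
    {"segment": "hand", "posture": "standing", "kind": "constant", "a1": 0, "b1": 0, "breakpoint": null, "a2": null, "b2": null, "minimum": 0, "r2": null},
    {"segment": "hand", "posture": "sitting", "kind": "constant", "a1": 0, "b1": 0, "breakpoint": null, "a2": null, "b2": null, "minimum": 0, "r2": null},
    {"segment": "hand", "posture": "generic", "kind": "constant", "a1": 0, "b1": 0, "breakpoint": null, "a2": null, "b2": null, "minimum": 0, "r2": null},
    {"segment": "chest", "posture": "standing", "kind": "linear", "a1": 2.975, "b1": -0.540, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.400, "r2": 0.879},
    {"segment": "chest", "posture": "sitting", "kind": "linear", "a1": 4.104, "b1": -0.773, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.415, "r2": 0.814},
    {"segment": "chest", "posture": "generic", "kind": "linear", "a1": 2.958, "b1": -0.297, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.400, "r2": 0.819},
    {"segment": "back", "posture": "standing", "kind": "linear", "a1": 3.668, "b1": -0.738, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.447, "r2": 0.853},
    {"segment": "back", "posture": "sitting", "kind": "linear", "a1": 1.963, "b1": 0.161, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.220, "r2": 0.605},
    {"segment": "back", "posture": "generic", "kind": "piecewise", "a1": 2.483, "b1": -0.097, "breakpoint": 1.050, "a2": 4.626, "b2": -2.347, "minimum": 0.220, "r2": 0.850},
    {"segment": "pelvis", "posture": "standing", "kind": "piecewise", "a1": 2.706, "b1": 0.698, "breakpoint": 0.916, "a2": 5.482, "b2": -1.846, "minimum": 1.153, "r2": 0.853},
    {"segment": "pelvis", "posture": "sitting", "kind": "linear", "a1": 1.412, "b1": 0.514, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.755, "r2": 0.748},
    {"segment": "pelvis", "posture": "generic", "kind": "piecewise", "a1": 2.256, "b1": 0.437, "breakpoint": 1.055, "a2": 7.047, "b2": -4.617, "minimum": 0.755, "r2": 0.836},
    {"segment": "shoulder", "posture": "standing", "kind": "linear", "a1": 2.230, "b1": -0.534, "breakpoint": null, "a2": null, "b2": null, "minimum": 0, "r2": 0.889},
    {"segment": "shoulder", "posture": "sitting", "kind": "linear", "a1": 2.510, "b1": -0.587, "breakpoint": null, "a2": null, "b2": null, "minimum": 0, "r2": 0.796},
    {"segment": "shoulder", "posture": "generic", "kind": "linear", "a1": 2.221, "b1": -0.459, "breakpoint": null, "a2": null, "b2": null, "minimum": 0, "r2": 0.870},
    {"segment": "arm", "posture": "standing", "kind": "linear", "a1": 2.580, "b1": -0.907, "breakpoint": null, "a2": null, "b2": null, "minimum": 0, "r2": 0.892},
    {"segment": "arm", "posture": "sitting", "kind": "linear", "a1": 1.993, "b1": -0.548, "breakpoint": null, "a2": null, "b2": null, "minimum": 0, "r2": 0.810},
    {"segment": "arm", "posture": "generic", "kind": "linear", "a1": 2.492, "b1": -0.840, "breakpoint": null, "a2": null, "b2": null, "minimum": 0, "r2": 0.891},
    {"segment": "thigh", "posture": "standing", "kind": "piecewise", "a1": 0.752, "b1": 0.321, "breakpoint": 1.390, "a2": 2.314, "b2": -1.849, "minimum": 0.316, "r2": 0.877},
    {"segment": "thigh", "posture": "sitting", "kind": "linear", "a1": 0.354, "b1": 0.504, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.280, "r2": 0.079},
    {"segment": "thigh", "posture": "generic", "kind": "piecewise", "a1": 0.370, "b1": 0.507, "breakpoint": 1.093, "a2": 1.999, "b2": -1.274, "minimum": 0.280, "r2": 0.777},
    {"segment": "leg", "posture": "standing", "kind": "piecewise", "a1": 2.794, "b1": -0.825, "breakpoint": 0.505, "a2": 0.648, "b2": 0.260, "minimum": 0, "r2": 0.856},
    {"segment": "leg", "posture": "sitting", "kind": "piecewise", "a1": 2.057, "b1": -0.548, "breakpoint": 0.420, "a2": 0.329, "b2": 0.178, "minimum": 0, "r2": 0.378},
    {"segment": "leg", "posture": "generic", "kind": "piecewise", "a1": 2.019, "b1": -0.552, "breakpoint": 0.450, "a2": 0.758, "b2": 0.016, "minimum": 0, "r2": 0.735},
    {"segment": "foot", "posture": "standing", "kind": "piecewise", "a1": 0.757, "b1": 0.182, "breakpoint": 1.590, "a2": 0.092, "b2": 1.241, "minimum": 0.180, "r2": 0.777},
    {"segment": "foot", "posture": "sitting", "kind": "linear", "a1": 0.496, "b1": 0.327, "breakpoint": null, "a2": null, "b2": null, "minimum": 0.211, "r2": 0.351},
    {"segment": "foot", "posture": "generic", "kind": "piecewise", "a1": 0.693, "b1": 0.217, "breakpoint": 1.677, "a2": 0.139, "b2": 1.146, "minimum": 0.180, "r2": 0.711}
  ]
}
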