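{
  "scale": "relative",
  "windows": [
    {"class_name": "lung_left",    "lo": 0.146, "hi": 0.214, "min_component_mm3": 2000, "side_constraint": "left_of_midline",  "priority": 30},
    {"class_name": "lung_right",   "lo": 0.146, "hi": 0.214, "min_component_mm3": 2000, "side_constraint": "right_of_midline", "priority": 31},
    {"class_name": "fat",          "lo": 0.318, "hi": 0.386, "min_component_mm3": 2000, "side_constraint": "none", "priority": 20},
    {"class_name": "muscle",       "lo": 0.420, "hi": 0.484, "min_component_mm3": 2000, "side_constraint": "none", "priority": 21},
    {"class_name": "liver",        "lo": 0.519, "hi": 0.587, "min_component_mm3": 2000, "side_constraint": "none", "priority": 22},
    {"class_name": "spleen",       "lo": 0.592, "hi": 0.660, "min_component_mm3": 1000, "side_constraint": "none", "priority": 23},
    {"class_name": "gallbladder",  "lo": 0.667, "hi": 0.735, "min_component_mm3": 300,  "side_constraint": "none", "priority": 40},
    {"class_name": "tumor",        "lo": 0.741, "hi": 0.809, "min_component_mm3": 300,  "side_constraint": "none", "priority": 45},
    {"class_name": "kidney_left",  "lo": 0.800, "hi": 0.868, "min_component_mm3": 1000, "side_constraint": "left_of_midline",  "priority": 50},
    {"class_name": "kidney_right", "lo": 0.800, "hi": 0.868, "min_component_mm3": 1000, "side_constraint": "right_of_midline", "priority": 51},
    {"class_name": "aorta",        "lo": 0.875, "hi": 0.943, "min_component_mm3": 500,  "side_constraint": "none", "priority": 35},
    {"class_name": "bone",         "lo": 0.940, "hi": 1.010, "min_component_mm3": 2000, "side_constraint": "none", "priority": 25}
  ]
}
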