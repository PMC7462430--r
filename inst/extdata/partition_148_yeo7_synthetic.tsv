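region_label	module
region_001_lh	Visual
region_002_lh	Visual
region_003_lh	Visual
region_004_lh	Visual
region_005_lh	Visual
region_006_lh	Visual
region_007_lh	Visual
region_008_lh	Visual
region_009_lh	Visual
region_010_lh	Visual
region_011_lh	Visual
region_012_lh	Visual
region_013_lh	Visual
region_014_lh	Visual
region_015_lh	Visual
region_016_lh	Visual
region_017_lh	Visual
region_018_lh	Visual
region_019_lh	Visual
region_020_lh	Visual
region_021_lh	Visual
region_022_lh	Visual
region_023_lh	Visual
region_024_lh	Visual
region_025_lh	Somatomotor
region_026_lh	Somatomotor
region_027_lh	Somatomotor
region_028_lh	Somatomotor
region_029_lh	Somatomotor
region_030_lh	Somatomotor
region_031_lh	Somatomotor
region_032_lh	Somatomotor
region_033_lh	Somatomotor
region_034_lh	Somatomotor
region_035_lh	Somatomotor
region_036_lh	Somatomotor
region_037_lh	Somatomotor
region_038_lh	Somatomotor
region_039_lh	Somatomotor
region_040_lh	Somatomotor
region_041_lh	Somatomotor
region_042_lh	Somatomotor
region_043_lh	Somatomotor
region_044_lh	Somatomotor
region_045_lh	Somatomotor
region_046_lh	Somatomotor
region_047_lh	DorsalAttention
region_048_lh	DorsalAttention
region_049_lh	DorsalAttention
region_050_lh	DorsalAttention
region_051_lh	DorsalAttention
region_052_lh	DorsalAttention
region_053_lh	DorsalAttention
region_054_lh	DorsalAttention
region_055_lh	DorsalAttention
region_056_lh	DorsalAttention
region_057_lh	DorsalAttention
region_058_lh	DorsalAttention
region_059_lh	DorsalAttention
region_060_lh	DorsalAttention
region_061_lh	DorsalAttention
region_062_lh	DorsalAttention
region_063_lh	DorsalAttention
region_064_lh	DorsalAttention
region_065_lh	VentralAttention
region_066_lh	VentralAttention
region_067_lh	VentralAttention
region_068_lh	VentralAttention
region_069_lh	VentralAttention
region_070_lh	VentralAttention
region_071_lh	VentralAttention
region_072_lh	VentralAttention
region_073_lh	VentralAttention
region_074_lh	VentralAttention
region_075_rh	VentralAttention
region_076_rh	VentralAttention
region_077_rh	VentralAttention
region_078_rh	VentralAttention
region_079_rh	VentralAttention
region_080_rh	VentralAttention
region_081_rh	Limbic
region_082_rh	Limbic
region_083_rh	Limbic
region_084_rh	Limbic
region_085_rh	Limbic
region_086_rh	Limbic
region_087_rh	Limbic
region_088_rh	Limbic
region_089_rh	Limbic
region_090_rh	Limbic
region_091_rh	Limbic
region_092_rh	Limbic
region_093_rh	Limbic
region_094_rh	Limbic
region_095_rh	Frontoparietal
region_096_rh	Frontoparietal
region_097_rh	Frontoparietal
region_098_rh	Frontoparietal
region_099_rh	Frontoparietal
region_100_rh	Frontoparietal
region_101_rh	Frontoparietal
region_102_rh	Frontoparietal
region_103_rh	Frontoparietal
region_104_rh	Frontoparietal
region_105_rh	Frontoparietal
region_106_rh	Frontoparietal
region_107_rh	Frontoparietal
region_108_rh	Frontoparietal
region_109_rh	Frontoparietal
region_110_rh	Frontoparietal
region_111_rh	Frontoparietal
region_112_rh	Frontoparietal
region_113_rh	Frontoparietal
region_114_rh	Frontoparietal
region_115_rh	Frontoparietal
region_116_rh	Frontoparietal
region_117_rh	Frontoparietal
region_118_rh	Frontoparietal
region_119_rh	Default
region_120_rh	Default
region_121_rh	Default
region_122_rh	Default
region_123_rh	Default
region_124_rh	Default
region_125_rh	Default
region_126_rh	Default
region_127_rh	Default
region_128_rh	Default
region_129_rh	Default
region_130_rh	Default
region_131_rh	Default
region_132_rh	Default
region_133_rh	Default
region_134_rh	Default
region_135_rh	Default
region_136_rh	Default
region_137_rh	Default
region_138_rh	Default
region_139_rh	Default
region_140_rh	Default
region_141_rh	Default
region_142_rh	Default
region_143_rh	Default
region_144_rh	Default
region_145_rh	Default
region_146_rh	Default
region_147_rh	Default
region_148_rh	Default
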