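"feature","family"
"firstorder_Energy","firstorder"
"firstorder_TotalEnergy","firstorder"
"firstorder_Entropy","firstorder"
"firstorder_Minimum","firstorder"
"firstorder_Percentile10","firstorder"
"firstorder_Percentile90","firstorder"
"firstorder_Maximum","firstorder"
"firstorder_Mean","firstorder"
"firstorder_Median","firstorder"
"firstorder_InterquartileRange","firstorder"
"firstorder_Range","firstorder"
"firstorder_MeanAbsoluteDeviation","firstorder"
"firstorder_RobustMeanAbsoluteDeviation","firstorder"
"firstorder_RootMeanSquared","firstorder"
"firstorder_Skewness","firstorder"
"firstorder_Kurtosis","firstorder"
"firstorder_Variance","firstorder"
"firstorder_Uniformity","firstorder"
"shape_MeshVolume","shape"
"shape_VoxelVolume","shape"
"shape_SurfaceArea","shape"
"shape_SurfaceVolumeRatio","shape"
"shape_Sphericity","shape"
"shape_Maximum3DDiameter","shape"
"shape_Maximum2DDiameterSlice","shape"
"shape_Maximum2DDiameterColumn","shape"
"shape_Maximum2DDiameterRow","shape"
"shape_MajorAxisLength","shape"
"shape_MinorAxisLength","shape"
"shape_LeastAxisLength","shape"
"shape_Elongation","shape"
"shape_Flatness","shape"
"glcm_Autocorrelation","glcm"
"glcm_JointAverage","glcm"
"glcm_ClusterProminence","glcm"
"glcm_ClusterShade","glcm"
"glcm_ClusterTendency","glcm"
"glcm_Contrast","glcm"
"glcm_Correlation","glcm"
"glcm_DifferenceAverage","glcm"
"glcm_DifferenceEntropy","glcm"
"glcm_DifferenceVariance","glcm"
"glcm_JointEnergy","glcm"
"glcm_JointEntropy","glcm"
"glcm_Imc1","glcm"
"glcm_Imc2","glcm"
"glcm_Idm","glcm"
"glcm_Idmn","glcm"
"glcm_Id","glcm"
"glcm_Idn","glcm"
"glcm_InverseVariance","glcm"
"glcm_MaximumProbability","glcm"
"glcm_SumAverage","glcm"
"glcm_SumEntropy","glcm"
"glcm_SumSquares","glcm"
"glcm_MCC","glcm"
"glrlm_ShortRunEmphasis","glrlm"
"glrlm_LongRunEmphasis","glrlm"
"glrlm_GrayLevelNonUniformity","glrlm"
"glrlm_GrayLevelNonUniformityNormalized","glrlm"
"glrlm_RunLengthNonUniformity","glrlm"
"glrlm_RunLengthNonUniformityNormalized","glrlm"
"glrlm_RunPercentage","glrlm"
"glrlm_GrayLevelVariance","glrlm"
"glrlm_RunVariance","glrlm"
"glrlm_RunEntropy","glrlm"
"glrlm_LowGrayLevelRunEmphasis","glrlm"
"glrlm_HighGrayLevelRunEmphasis","glrlm"
"glrlm_ShortRunLowGrayLevelEmphasis","glrlm"
"glrlm_ShortRunHighGrayLevelEmphasis","glrlm"
"glrlm_LongRunLowGrayLevelEmphasis","glrlm"
"glrlm_LongRunHighGrayLevelEmphasis","glrlm"
"glszm_SmallAreaEmphasis","glszm"
"glszm_LargeAreaEmphasis","glszm"
"glszm_GrayLevelNonUniformity","glszm"
"glszm_GrayLevelNonUniformityNormalized","glszm"
"glszm_SizeZoneNonUniformity","glszm"
"glszm_SizeZoneNonUniformityNormalized","glszm"
"glszm_ZonePercentage","glszm"
"glszm_GrayLevelVariance","glszm"
"glszm_ZoneVariance","glszm"
"glszm_ZoneEntropy","glszm"
"glszm_LowGrayLevelZoneEmphasis","glszm"
"glszm_HighGrayLevelZoneEmphasis","glszm"
"glszm_SmallAreaLowGrayLevelEmphasis","glszm"
"glszm_SmallAreaHighGrayLevelEmphasis","glszm"
"glszm_LargeAreaLowGrayLevelEmphasis","glszm"
"glszm_LargeAreaHighGrayLevelEmphasis","glszm"
"gldm_SmallDependenceEmphasis","gldm"
"gldm_LargeDependenceEmphasis","gldm"
"gldm_GrayLevelNonUniformity","gldm"
"gldm_DependenceNonUniformity","gldm"
"gldm_DependenceNonUniformityNormalized","gldm"
"gldm_GrayLevelVariance","gldm"
"gldm_DependenceVariance","gldm"
"gldm_DependenceEntropy","gldm"
"gldm_LowGrayLevelEmphasis","gldm"
"gldm_HighGrayLevelEmphasis","gldm"
"gldm_SmallDependenceLowGrayLevelEmphasis","gldm"
"gldm_SmallDependenceHighGrayLevelEmphasis","gldm"
"gldm_LargeDependenceLowGrayLevelEmphasis","gldm"
"gldm_LargeDependenceHighGrayLevelEmphasis","gldm"
"ngtdm_Coarseness","ngtdm"
"ngtdm_Contrast","ngtdm"
"ngtdm_Busyness","ngtdm"
"ngtdm_Complexity","ngtdm"
"ngtdm_Strength","ngtdm"
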