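parameter,condition,side,n,bias,ci_lo,ci_hi,loa_lo,loa_hi,anomalous
step_length,com,L,20,14.215,6.787,21.643,-16.895,45.325,0
step_length,com,R,20,13.92,6.827,21.013,-15.785,43.625,0
step_length,com,LR,20,14.068,9.168,18.967,-15.957,44.092,0
step_length,max,L,20,9.647,-10.120,29.415,-70.737,90.031,0
step_length,max,R,20,11.25,-1.528,24.028,-39.114,61.614,0
step_length,max,LR,20,10.427,-0.897,21.751,-56.140,76.994,0
step_length,tandem,L,20,5.816,-6.400,18.032,-43.860,55.491,0
step_length,tandem,R,20,-0.205,-8.833,8.422,-35.289,34.879,0
step_length,tandem,LR,20,2.805,-4.379,9.989,-40.032,45.643,0
gait_speed,com,L,20,0.016,-0.002,0.034,-0.060,0.092,0
gait_speed,com,R,20,0.017,0.006,0.027,-0.029,0.062,0
gait_speed,com,LR,20,0.016,0.006,0.026,-0.045,0.078,0
gait_speed,max,L,20,0.036,0.005,0.068,-0.091,0.163,0
gait_speed,max,R,20,0.041,0.014,0.067,-0.063,0.144,0
gait_speed,max,LR,20,0.038,0.019,0.058,-0.076,0.153,0
gait_speed,tandem,L,20,-0.013,-0.035,0.007,-0.099,0.071,0
gait_speed,tandem,R,20,0.001,-0.016,0.017,-0.067,0.068,0
gait_speed,tandem,LR,20,-0.007,-0.020,0.006,-0.084,0.071,0
stride_time,com,L,20,-0.005,-0.015,0.005,-0.046,0.036,0
stride_time,com,R,20,0.002,-0.008,0.012,-0.041,0.045,0
stride_time,com,LR,20,-0.001,-0.008,0.006,-0.043,0.041,0
stride_time,max,L,20,-0.011,-0.026,0.004,-0.071,0.049,0
stride_time,max,R,20,-0.004,-0.013,0.005,-0.039,0.031,0
stride_time,max,LR,20,-0.008,-0.016,0.001,-0.057,0.041,0
stride_time,tandem,L,20,-0.007,-0.028,0.015,-0.094,0.081,0
stride_time,tandem,R,20,-0.004,-0.016,0.007,-0.052,0.043,0
stride_time,tandem,LR,20,-0.005,-0.017,0.006,-0.075,0.064,0
stride_length,com,L,20,8.2,-8.593,24.993,-62.126,78.526,0
stride_length,com,R,20,19.65,8.450,30.850,-27.253,66.553,0
stride_length,com,LR,20,13.925,4.121,23.729,-46.162,74.012,0
stride_length,max,L,20,8.632,-22.800,40.063,-119.184,136.447,0
stride_length,max,R,20,26.222,3.001,49.443,-65.300,117.744,0
stride_length,max,LR,20,-0.877,-0.898,-0.856,-1.000,-0.754,1
stride_length,tandem,L,20,-14.895,-34.194,4.405,-93.376,63.587,0
stride_length,tandem,R,20,-4.368,-26.311,17.572,-93.599,84.862,0
stride_length,tandem,LR,20,-9.632,-23.641,4.378,-93.173,73.910,0
tla_angle,com,L,20,1.515,1.088,1.942,-0.273,3.303,0
tla_angle,com,R,20,0.315,-0.348,0.978,-2.461,3.091,0
tla_angle,com,LR,20,0.915,0.492,1.338,-1.679,3.509,0
tla_angle,max,L,20,1.574,1.098,2.049,-0.361,3.508,0
tla_angle,max,R,20,0.917,0.170,1.663,-2.025,3.858,0
tla_angle,max,LR,20,1.254,0.824,1.683,-1.272,3.780,0
tla_angle,tandem,L,20,1.342,0.858,1.827,-0.628,3.312,0
tla_angle,tandem,R,20,0.989,0.418,1.561,-1.333,3.312,0
tla_angle,tandem,LR,20,1.166,0.805,1.527,-0.987,3.319,0
hip_flexion_angle,com,L,20,3.48,0.718,6.242,-8.086,15.046,0
hip_flexion_angle,com,R,20,0.29,-2.762,3.342,-12.490,13.070,0
hip_flexion_angle,com,LR,20,1.885,-0.145,3.915,-10.556,14.326,0
hip_extension_angle,com,L,20,-1.695,-4.487,1.097,-13.387,9.997,0
hip_extension_angle,com,R,20,1.98,-0.924,4.884,-10.180,14.140,0
hip_extension_angle,com,LR,20,0.143,-1.869,2.154,-12.184,12.469,0
hip_flexion_angle,max,L,20,5.347,2.085,8.610,-7.920,18.614,0
hip_flexion_angle,max,R,20,0.089,-3.407,3.585,-13.691,13.869,0
hip_flexion_angle,max,LR,20,2.789,0.354,5.224,-11.527,17.105,0
hip_extension_angle,max,L,20,-0.337,-3.357,2.683,-12.619,11.945,0
hip_extension_angle,max,R,20,0.089,-3.407,3.585,-13.691,13.869,0
hip_extension_angle,max,LR,20,-1.008,-3.222,1.206,-14.022,12.006,0
hip_flexion_angle,tandem,L,20,4.463,1.305,7.621,-8.379,17.305,0
hip_flexion_angle,tandem,R,20,0.837,-2.603,4.276,-13.150,14.823,0
hip_flexion_angle,tandem,LR,20,-2.95,-5.412,-0.488,-17.629,11.729,1
hip_extension_angle,tandem,L,20,-0.037,-3.296,3.222,-13.291,13.217,0
hip_extension_angle,tandem,R,20,0.658,-2.566,3.882,-12.451,13.767,0
hip_extension_angle,tandem,LR,20,0.311,-1.873,2.494,-12.710,13.331,0
knee_flexion_angle,com,L,20,0.71,-2.695,4.115,-13.550,14.970,0
knee_flexion_angle,com,R,20,-0.035,-4.716,4.646,-19.639,19.569,0
knee_flexion_angle,com,LR,20,0.338,-2.426,3.101,-16.599,17.274,0
knee_extension_angle,com,L,20,-3.53,-6.060,1.000,-14.123,7.063,1
knee_extension_angle,com,R,20,-1.22,-4.769,2.329,-16.083,13.643,0
knee_extension_angle,com,LR,20,-2.375,-4.487,-0.263,-15.319,10.569,0
knee_flexion_angle,max,L,20,2.311,-0.828,5.449,-10.451,15.072,0
knee_flexion_angle,max,R,20,-6.317,-13.728,1.095,-35.528,22.895,0
knee_flexion_angle,max,LR,20,-1.886,-5.904,2.131,-0.725,4.951,1
knee_extension_angle,max,L,20,-3.521,-6.160,-0.882,-14.252,7.210,0
knee_extension_angle,max,R,20,-9.739,-15.514,-3.963,-32.502,13.025,0
knee_extension_angle,max,LR,20,-6.546,-9.685,-3.407,-24.996,11.904,0
knee_flexion_angle,tandem,L,20,1.089,-1.922,34.101,-11.158,13.337,1
knee_flexion_angle,tandem,R,20,-2.474,-6.716,1.768,-19.724,14.777,0
knee_flexion_angle,tandem,LR,20,-0.692,-3.237,1.853,-15.867,14.482,0
knee_extension_angle,tandem,L,20,-2.289,-5.220,0.641,-14.208,9.629,0
knee_extension_angle,tandem,R,20,-3.611,-7.851,0.630,-20.853,13.632,0
knee_extension_angle,tandem,LR,20,-2.95,-5.412,-0.488,-17.629,11.729,0
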