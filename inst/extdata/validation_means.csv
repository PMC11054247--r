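parameter,units,condition,side,vicon_mean,vicon_sd,imasen_mean,imasen_sd,diff
step_length,mm,com,L,699.6,48.7,685.4,47.2,-14.2
step_length,mm,com,R,696.2,49.4,682.2,48.3,-13.9
step_length,mm,com,LR,697.9,48.4,683.8,47.1,-14.1
step_length,mm,max,L,790.5,55.7,780.8,63.6,-9.6
step_length,mm,max,R,799,51.6,787.7,50.1,-11.2
step_length,mm,max,LR,794.6,53.2,784.2,56.7,-10.4
step_length,mm,tandem,L,663.9,77,658.1,78.1,-5.8
step_length,mm,tandem,R,663.1,71.3,663.3,69.5,0.2
step_length,mm,tandem,LR,663.5,73.2,660.7,73,-2.8
gait_speed,m/s,com,L,1.38,0.12,1.36,0.11,-0.02
gait_speed,m/s,com,R,1.38,0.12,1.37,0.11,-0.02
gait_speed,m/s,com,LR,1.38,0.12,1.37,0.11,-0.02
gait_speed,m/s,max,L,1.85,0.18,1.82,0.17,-0.03
gait_speed,m/s,max,R,1.86,0.17,1.82,0.13,-0.04
gait_speed,m/s,max,LR,1.86,0.17,1.82,0.15,-0.04
gait_speed,m/s,tandem,L,1.23,0.23,1.24,0.24,0.01
gait_speed,m/s,tandem,R,1.25,0.23,1.24,0.21,0
gait_speed,m/s,tandem,LR,1.24,0.23,1.24,0.22,0.01
stride_time,s,com,L,1.009,0.046,1.013,0.036,0.005
stride_time,s,com,R,1.023,0.045,1.021,0.038,-0.002
stride_time,s,com,LR,1.016,0.046,1.017,0.037,0.001
stride_time,s,max,L,0.858,0.068,0.869,0.064,0.011
stride_time,s,max,R,0.874,0.063,0.878,0.059,0.004
stride_time,s,max,LR,0.866,0.065,0.873,0.061,0.008
stride_time,s,tandem,L,1.092,0.142,1.099,0.166,0.007
stride_time,s,tandem,R,1.086,0.124,1.091,0.125,0.004
stride_time,s,tandem,LR,1.089,0.131,1.095,0.145,0.005
stride_length,mm,com,L,1385.5,96.6,1377.1,92.6,-8.4
stride_length,mm,com,R,1413,92.5,1393.2,92.4,-19.7
stride_length,mm,com,LR,1399.2,94.4,1385.2,91.7,-14
stride_length,mm,max,L,1580,94.3,1571.2,119.3,-8.7
stride_length,mm,max,R,1615.3,109.8,1589,89.2,-26.3
stride_length,mm,max,LR,1597.1,102.3,1579.9,104.6,-17.3
stride_length,mm,tandem,L,1313.9,141.5,1328.7,146.1,14.8
stride_length,mm,tandem,R,1327.9,155.5,1332.3,136.1,4.4
stride_length,mm,tandem,LR,1320.9,146.8,1330.5,139.3,9.6
tla_angle,deg,com,L,23.6,2.6,22.1,2.4,-1.5
tla_angle,deg,com,R,23.6,2.5,23.2,2.1,-0.3
tla_angle,deg,com,LR,23.6,2.5,22.7,2.3,-0.9
tla_angle,deg,max,L,27.2,2.5,25.6,2.1,-1.6
tla_angle,deg,max,R,26.9,2.8,25.9,2.2,-0.9
tla_angle,deg,max,LR,27,2.6,25.8,2.1,-1.3
tla_angle,deg,tandem,L,22.1,3.2,20.8,2.7,-1.3
tla_angle,deg,tandem,R,22.1,3.3,21.1,3.1,-1
tla_angle,deg,tandem,LR,22.1,3.2,21,2.9,-1.2
hip_flexion_angle,deg,com,L,31,6.1,27.5,1.9,-3.5
hip_flexion_angle,deg,com,R,32.5,6.1,32.2,3,-0.3
hip_flexion_angle,deg,com,LR,31.7,6.1,29.8,3.5,-1.9
hip_flexion_angle,deg,max,L,33.9,6.4,28.6,2.5,-5.4
hip_flexion_angle,deg,max,R,34.7,6.1,34.6,2.7,-0.1
hip_flexion_angle,deg,max,LR,34.3,6.2,31.5,4,-2.8
hip_flexion_angle,deg,tandem,L,31.6,6.2,27.1,2.6,-4.5
hip_flexion_angle,deg,tandem,R,33.2,5.7,32.4,3.8,-0.8
hip_flexion_angle,deg,tandem,LR,32.4,5.9,29.8,4.2,-2.7
hip_flexion_phase,pct,com,L,13,5.6,6.4,3.8,-6.6
hip_flexion_phase,pct,com,R,12,4.7,6,2.9,-6
hip_flexion_phase,pct,com,LR,12.5,5.2,6.2,3.3,-6.3
hip_flexion_phase,pct,max,L,14.3,6.1,9.3,4,-5
hip_flexion_phase,pct,max,R,14.7,6.4,9.3,3.3,-5.4
hip_flexion_phase,pct,max,LR,14.5,6.2,9.3,3.7,-5.2
hip_flexion_phase,pct,tandem,L,10.4,5.3,5,4,-5.4
hip_flexion_phase,pct,tandem,R,10.9,4.8,4.8,2.3,-6.1
hip_flexion_phase,pct,tandem,LR,10.7,5,4.9,3.2,-5.8
hip_extension_angle,deg,com,L,-14.1,6.7,-12.4,3.1,1.7
hip_extension_angle,deg,com,R,-13.3,5.8,-15.3,2.7,-2
hip_extension_angle,deg,com,LR,-13.7,6.2,-13.8,3.2,-0.1
hip_extension_angle,deg,max,L,-16.1,6.9,-15.7,2.7,0.3
hip_extension_angle,deg,max,R,-16.6,6.8,-14.9,3.9,1.7
hip_extension_angle,deg,max,LR,-16.3,6.8,-15.3,3.3,1
hip_extension_angle,deg,tandem,L,-12.2,8.2,-12.1,3.1,0
hip_extension_angle,deg,tandem,R,-12.5,6.4,-13.1,4.8,-0.7
hip_extension_angle,deg,tandem,LR,-12.3,7.3,-12.6,4,-0.3
hip_extension_phase,pct,com,L,70.8,1.8,66.4,1.6,-4.5
hip_extension_phase,pct,com,R,71.1,1.4,67.1,1.5,-4
hip_extension_phase,pct,com,LR,70.9,1.6,66.7,1.6,-4.2
hip_extension_phase,pct,max,L,69.5,2,65.4,1.4,-4.2
hip_extension_phase,pct,max,R,69.5,1.8,65.6,1,-3.9
hip_extension_phase,pct,max,LR,69.5,1.8,65.5,1.3,-4
hip_extension_phase,pct,tandem,L,71.7,2.2,67.5,2.2,-4.2
hip_extension_phase,pct,tandem,R,71.6,2,67.5,1.8,-4.1
hip_extension_phase,pct,tandem,LR,71.7,2.1,67.5,2,-4.2
knee_flexion_angle,deg,com,L,65.9,8.6,65.2,2.1,-0.7
knee_flexion_angle,deg,com,R,65.3,11.4,65.3,4.1,0
knee_flexion_angle,deg,com,LR,65.6,9.9,65.3,3.2,-0.3
knee_flexion_angle,deg,max,L,66.8,7.6,64.5,3.1,-2.3
knee_flexion_angle,deg,max,R,63.5,13,69.8,5.6,6.3
knee_flexion_angle,deg,max,LR,65.2,10.6,67.1,5.2,1.9
knee_flexion_angle,deg,tandem,L,65.4,7.1,64.3,3.1,-1.1
knee_flexion_angle,deg,tandem,R,65.2,10.4,67.7,6.4,2.5
knee_flexion_angle,deg,tandem,LR,65.3,8.8,66,5.3,0.7
knee_flexion_phase,pct,com,L,90.7,1.3,88.3,1.1,-2.5
knee_flexion_phase,pct,com,R,91,1.1,89.3,0.9,-1.6
knee_flexion_phase,pct,com,LR,90.9,1.2,88.8,1.1,-2.1
knee_flexion_phase,pct,max,L,90.2,1.3,87.6,1,-2.7
knee_flexion_phase,pct,max,R,90.3,1.3,88.5,1.1,-1.8
knee_flexion_phase,pct,max,LR,90.3,1.3,88,1.2,-2.2
knee_flexion_phase,pct,tandem,L,91.7,1.4,88.7,1.1,-3
knee_flexion_phase,pct,tandem,R,92,1.1,89.6,1.3,-2.4
knee_flexion_phase,pct,tandem,LR,91.8,1.2,89.1,1.3,-2.7
knee_extension_angle,deg,com,L,6,7,9.5,3.9,3.5
knee_extension_angle,deg,com,R,6.5,7.3,7.7,4.5,1.2
knee_extension_angle,deg,com,LR,6.2,7.1,8.6,4.3,2.4
knee_extension_angle,deg,max,L,5.7,6.3,9.3,3.8,3.5
knee_extension_angle,deg,max,R,3.6,8.7,13.3,6.9,9.7
knee_extension_angle,deg,max,LR,4.7,7.5,11.2,5.8,6.5
knee_extension_angle,deg,tandem,L,6.4,7.6,8.7,5.5,2.3
knee_extension_angle,deg,tandem,R,5.6,8.5,9.3,7.8,3.6
knee_extension_angle,deg,tandem,LR,6,8,9,6.6,3
knee_extension_phase,pct,com,L,57,2.1,54,2,-3
knee_extension_phase,pct,com,R,57,2,57.2,1.8,0.2
knee_extension_phase,pct,com,LR,57,2,55.6,2.5,-1.4
knee_extension_phase,pct,max,L,57.5,1.6,55,1.7,-2.5
knee_extension_phase,pct,max,R,57.6,1.7,57.3,1.3,-0.4
knee_extension_phase,pct,max,LR,57.5,1.6,56.1,1.9,-1.5
knee_extension_phase,pct,tandem,L,54.6,3.9,52.1,4.8,-2.5
knee_extension_phase,pct,tandem,R,54.8,4.1,55.7,3.2,0.9
knee_extension_phase,pct,tandem,LR,54.7,4,53.9,4.4,-0.8
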