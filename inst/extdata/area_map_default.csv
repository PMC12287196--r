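original_segment,area_fraction,target_segment
head,0.070,head
neck,0.020,neck
chest,0.130,chest
back,0.130,back
pelvis,0.090,pelvis
left_shoulder,0.025,shoulder
right_shoulder,0.025,shoulder
left_arm,0.050,arm
right_arm,0.050,arm
left_hand,0.025,hand
right_hand,0.025,hand
left_thigh,0.095,thigh
right_thigh,0.095,thigh
left_leg,0.060,leg
right_leg,0.060,leg
left_foot,0.035,foot
right_foot,0.035,foot
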