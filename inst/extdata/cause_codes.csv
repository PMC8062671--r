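code,group,version
lightning,natural,1
railroad,human_transportation,1
vehicle,human_transportation,1
aircraft,human_transportation,1
equipment_use,human_activity,1
smoking,human_activity,1
campfire,human_activity,1
debris_burning,human_activity,1
arson,human_activity,1
playing_with_fire,human_activity,1
firefighter_training,human_activity,1
non_firefighter_training,human_activity,1
escaped_prescribed_burn,human_activity,1
illegal_campfire,human_activity,1
powerline,human_construction,1
structure,human_construction,1
miscellaneous,miscellaneous,1
unknown,unknown,1
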