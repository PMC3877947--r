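stratum,old_category,new_category,count
event,1,1,1
event,1,2,3
event,1,3,3
event,1,4,3
event,2,1,2
event,2,2,2
event,2,3,4
event,2,4,5
event,3,1,2
event,3,2,1
event,3,3,5
event,3,4,8
event,4,1,1
event,4,2,3
event,4,3,11
event,4,4,115
nonevent,1,1,96
nonevent,1,2,31
nonevent,1,3,14
nonevent,1,4,4
nonevent,2,1,41
nonevent,2,2,14
nonevent,2,3,5
nonevent,2,4,2
nonevent,3,1,34
nonevent,3,2,19
nonevent,3,3,9
nonevent,3,4,5
nonevent,4,1,35
nonevent,4,2,11
nonevent,4,3,8
nonevent,4,4,6
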