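stratum,old_category,new_category,count
event,1,1,3
event,1,2,0
event,1,3,0
event,1,4,0
event,2,1,6
event,2,2,28
event,2,3,0
event,2,4,0
event,3,1,4
event,3,2,48
event,3,3,40
event,3,4,0
event,4,1,0
event,4,2,1
event,4,3,10
event,4,4,29
nonevent,1,1,43
nonevent,1,2,4
nonevent,1,3,0
nonevent,1,4,0
nonevent,2,1,129
nonevent,2,2,31
nonevent,2,3,0
nonevent,2,4,0
nonevent,3,1,63
nonevent,3,2,38
nonevent,3,3,9
nonevent,3,4,0
nonevent,4,1,7
nonevent,4,2,7
nonevent,4,3,3
nonevent,4,4,0
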