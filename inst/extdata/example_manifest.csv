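slice_id,region_label,quality_label,image_path
a,1,0,a.png
b,2,1,b.png
c,1,0,c.png
d,3,1,d.png
e,2,1,e.png
f,1,0,f.png
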