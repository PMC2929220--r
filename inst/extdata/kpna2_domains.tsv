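reference_id	domain	start	end
KPNA2	IBB	1	95
KPNA2	ARM1	100	141
KPNA2	ARM2	142	184
KPNA2	ARM3	185	226
KPNA2	ARM4	227	268
KPNA2	ARM5	269	310
KPNA2	ARM6	311	352
KPNA2	ARM7	353	394
KPNA2	ARM8	395	437
KPNA2	ARM9	438	479
KPNA2	ARM10	480	521
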