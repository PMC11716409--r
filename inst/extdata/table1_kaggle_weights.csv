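position,field,group,weight,tabular_only
1,Subtitle,completeness,1.17,FALSE
2,Tag,completeness,1.17,FALSE
3,Description,completeness,1.17,FALSE
4,Cover Image,completeness,0.59,FALSE
5,Source/Provenance,credibility,0.59,FALSE
6,Public Notebook,credibility,0.59,FALSE
7,Update Frequency,credibility,0.59,FALSE
8,License,compatibility,1.18,FALSE
9,File Format,compatibility,1.18,FALSE
10,File Description,compatibility,1.18,FALSE
11,Column Description,compatibility,0.59,TRUE
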