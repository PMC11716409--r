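venus_qid,ai_act_requirement,datasheets_questions,kaggle_fields,additional_desiderata
Q1,origin of data; purpose of data collection,1;2;21,Source/Provenance,
Q2,privacy & data protection,15;18;28;29;46,License,
Q3,"geographic, contextual, & functional setting",22;25,,
Q4,information represented by the data,9,Column Description,
Q5,possible biases,17,,
Q6,errors & shortcomings,10;13,,
Q7,errors & shortcomings,13,,
Q8,data preparation,33;40,,
Q9,,,,permanent documentation & external validation
Q10,,44;45;46,,open data
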