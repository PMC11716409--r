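dataset_id,question_id,score
D1,Q1,0.3
D1,Q2,0.35
D1,Q3,0.15
D1,Q4,0.4
D1,Q5,0.5
D1,Q6,0
D1,Q7,0
D1,Q8,0
D1,Q9,0
D1,Q10,1
D2,Q1,1
D2,Q2,0.6
D2,Q3,0.75
D2,Q4,0.85
D2,Q5,0.63
D2,Q6,0
D2,Q7,0
D2,Q8,0.65
D2,Q9,1
D2,Q10,1
D3,Q1,1
D3,Q2,1
D3,Q3,1
D3,Q4,1
D3,Q5,0.5
D3,Q6,0.3
D3,Q7,0.05
D3,Q8,0.6
D3,Q9,1
D3,Q10,1
D4,Q1,0.65
D4,Q2,0
D4,Q3,0.7
D4,Q4,0.9
D4,Q5,0.95
D4,Q6,0.3
D4,Q7,0
D4,Q8,0.32
D4,Q9,0.9
D4,Q10,0.3
D5,Q1,0.8
D5,Q2,0.15
D5,Q3,0.6
D5,Q4,1
D5,Q5,0.7
D5,Q6,0
D5,Q7,0.05
D5,Q8,0.42
D5,Q9,1
D5,Q10,1
D6,Q1,1
D6,Q2,0.45
D6,Q3,0.5
D6,Q4,1
D6,Q5,0.5
D6,Q6,0
D6,Q7,0.15
D6,Q8,0.32
D6,Q9,0.5
D6,Q10,1
D7,Q1,1
D7,Q2,0.7
D7,Q3,1
D7,Q4,1
D7,Q5,0.85
D7,Q6,0.2
D7,Q7,0.35
D7,Q8,1
D7,Q9,1
D7,Q10,1
D8,Q1,0.6
D8,Q2,0.25
D8,Q3,0.35
D8,Q4,0.6
D8,Q5,0
D8,Q6,0
D8,Q7,0
D8,Q8,0.4
D8,Q9,0.5
D8,Q10,1
D9,Q1,1
D9,Q2,0.25
D9,Q3,1
D9,Q4,0.42
D9,Q5,0.4
D9,Q6,0.9
D9,Q7,1
D9,Q8,1
D9,Q9,1
D9,Q10,1
D10,Q1,1
D10,Q2,0.5
D10,Q3,0.6
D10,Q4,1
D10,Q5,0.5
D10,Q6,0.1
D10,Q7,0
D10,Q8,0.9
D10,Q9,1
D10,Q10,1
D11,Q1,0.9
D11,Q2,0.45
D11,Q3,0.75
D11,Q4,1
D11,Q5,0.05
D11,Q6,0.3
D11,Q7,0.2
D11,Q8,0.58
D11,Q9,0.75
D11,Q10,0.75
D12,Q1,1
D12,Q2,0.45
D12,Q3,0.6
D12,Q4,1
D12,Q5,0
D12,Q6,0.1
D12,Q7,0.1
D12,Q8,0.58
D12,Q9,1
D12,Q10,0.6
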