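chr3	181900000	185500000	T15
chr3	180200000	184600000	T35
chr3	181000000	185000000	T04
chr3	181500000	186000000	T10
chr3	180500000	184800000	T22
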