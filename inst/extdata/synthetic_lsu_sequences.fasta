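>LSU1
MQAERKEKKARREQQQALAAAAAQLAQQLAQAAQKEEQQQEQAAQAAQQQEALCQQLQALQQQALAQQAQKAQAQAQLAQQAAALQAQQARRAAKEEKEQ
>LSU2
MREEAKKEERERQAAQALQQAAEKAAAQLQQQAAAQLAQAAKKQAAQQQQEQLCAALQALAAQALQQAQAQERQQQALQAALAQLAAQQAEQEEQRARRR
>LSU3
MQQEAKAAQRAKQAAQQLAAAQAALQQQLQAAQEREQERRQQAEQAAAAAEQLCQALAALAAAALAQQAQQQRAQQQLQQAQAQLQQQAAQQRRARQAEA
>LSU4
MEKKEAQERRKEQAAAQLAAQARQQAAALAQAAAQALQAAARQERRAQQQEALCQALAALQAQQLQQQQAAARQQAALQQALAAQQQRQARREQKARRKQ
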