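SUBJECT_CUI	PREDICATE	OBJECT_CUI
C01	TREATS	C02
C02	CAUSES	C03
C01	PART_OF	C03
C04	LOCATION_OF	C01
C02	NEG_TREATS	C03
C01	TREATS	C99
C98	AFFECTS	C02
C03	INTERACTS_WITH	C04
C04	TREATS	C02
C01	AFFECTS	C04
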