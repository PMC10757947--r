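name	n_acyl_positions	compartment	is_membrane_diacyl
DGDG	2	plastidic	TRUE
MGDG	2	plastidic	TRUE
SQDG	2	plastidic	TRUE
PG	2	plastidic	TRUE
PA	2	extra-plastidic	TRUE
PC	2	extra-plastidic	TRUE
PE	2	extra-plastidic	TRUE
PE-N	2	extra-plastidic	FALSE
PI	2	extra-plastidic	TRUE
PS	2	extra-plastidic	TRUE
LPC	1	extra-plastidic	FALSE
LPE	1	extra-plastidic	FALSE
MGMG	1	plastidic	FALSE
DGMG	1	plastidic	FALSE
TrGDG	2	plastidic	FALSE
acMGDG	3	plastidic	FALSE
DG	2	neutral-storage	FALSE
TG	3	neutral-storage	FALSE
SE	1	sterol	FALSE
SG	0	sterol	FALSE
ASG	1	sterol	FALSE
GSL	NA	sphingolipid	FALSE
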