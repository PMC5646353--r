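label	x	y	z
Fp1	-0.293893	0.904508	0.309017
Fp2	0.293893	0.904508	0.309017
F3	-0.433027	0.645416	0.629226
F4	0.433027	0.645416	0.629226
C3	-0.587785	0	0.809017
C4	0.587785	0	0.809017
P3	-0.433027	-0.645416	0.629226
P4	0.433027	-0.645416	0.629226
O1	-0.293893	-0.904508	0.309017
O2	0.293893	-0.904508	0.309017
F7	-0.769421	0.559017	0.309017
F8	0.769421	0.559017	0.309017
T7	-0.951057	0	0.309017
T8	0.951057	0	0.309017
P7	-0.769421	-0.559017	0.309017
P8	0.769421	-0.559017	0.309017
Iz	0	-1	0
Cz	0	0	1
Pz	0	-0.587785	0.809017
FC1	-0.283943	0.350699	0.892405
FC2	0.283943	0.350699	0.892405
CP1	-0.283943	-0.350699	0.892405
CP2	0.283943	-0.350699	0.892405
FC5	-0.756469	0.342798	0.556996
FC6	0.756469	0.342798	0.556996
CP5	-0.756469	-0.342798	0.556996
CP6	0.756469	-0.342798	0.556996
TP9	-0.97494	-0.219771	0.034524
TP10	0.97494	-0.219771	0.034524
Fpz	0	0.951057	0.309017
Oz	0	-0.951057	0.309017
FT9	-0.97494	0.219771	0.034524
FT10	0.97494	0.219771	0.034524
PO9	-0.671788	-0.708959	0.214656
PO10	0.671788	-0.708959	0.214656
C1	-0.309017	0	0.951057
C2	0.309017	0	0.951057
PO1	-0.14903	-0.830485	0.536735
PO2	0.14903	-0.830485	0.536735
Fz	0	0.587785	0.809017
AFz	0	0.809017	0.587785
F5	-0.618731	0.619753	0.482782
F6	0.618731	0.619753	0.482782
FT7	-0.904508	0.293893	0.309017
FT8	0.904508	0.293893	0.309017
FC3	-0.543523	0.362291	0.757184
FC4	0.543523	0.362291	0.757184
C5	-0.809017	0	0.587785
C6	0.809017	0	0.587785
TP7	-0.904508	-0.293893	0.309017
TP8	0.904508	-0.293893	0.309017
CP3	-0.543523	-0.362291	0.757184
CP4	0.543523	-0.362291	0.757184
P5	-0.618731	-0.619753	0.482782
P6	0.618731	-0.619753	0.482782
OI1	-0.038773	-0.986871	0.156788
OI2	0.038773	-0.986871	0.156788
FCz	0	0.309017	0.951057
CPz	0	-0.309017	0.951057
POz	0	-0.809017	0.587785
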