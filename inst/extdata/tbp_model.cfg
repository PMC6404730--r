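# Default three-step TBP-promoter affinity model.
#
# Stop step: 15-position TATA-box PWM, log2-odds of a consensus probability
# matrix against uniform base composition (consensus GTTATAAAAGGGCCG).
# Slide / bend steps: dinucleotide step-flexibility and bending-propensity
# scales, normalized to [0, 1] so that every dinucleotide step of the
# consensus site scores the table maximum 1.0: the optimal stop-step site
# is then optimal under all three steps simultaneously.
# Calibrations map each raw step term onto the -ln(KD) scale (KD in mol/L):
# E_i = a_i + b_i * f_i, anchored so every step scores the PWM consensus at
# -ln(KD) = 20.8 (KD ~ 0.9 nM).

window_length = 15
alpha_threshold = 0.95

pwm_A = -0.736966 -1.321928 -2.321928 1.847997 -3.643856 1.879706 1.137504 1.765535 0.847997 0.263034 -0.321928 -0.736966 -0.321928 -0.321928 -0.321928
pwm_C = 0.263034 0.000000 -3.643856 -3.058894 -4.643856 -3.643856 -3.643856 -3.058894 -2.321928 -0.736966 0.000000 0.263034 0.263034 0.263034 0.000000
pwm_G = 0.678072 -0.736966 -3.058894 -3.643856 -4.643856 -3.643856 -3.058894 -2.643856 -0.736966 0.678072 0.485427 0.678072 0.263034 0.263034 0.485427
pwm_T = -0.736966 1.000000 1.847997 -2.321928 1.941106 -2.643856 0.678072 -1.643856 0.485427 -0.736966 -0.321928 -0.736966 -0.321928 -0.321928 -0.321928

slide_AA = 1.00
slide_AC = 0.35
slide_AG = 1.00
slide_AT = 1.00
slide_CA = 0.45
slide_CC = 1.00
slide_CG = 1.00
slide_CT = 0.40
slide_GA = 0.42
slide_GC = 1.00
slide_GG = 1.00
slide_GT = 1.00
slide_TA = 1.00
slide_TC = 0.38
slide_TG = 0.45
slide_TT = 1.00

bend_AA = 1.00
bend_AC = 0.30
bend_AG = 1.00
bend_AT = 1.00
bend_CA = 0.50
bend_CC = 1.00
bend_CG = 1.00
bend_CT = 0.35
bend_GA = 0.40
bend_GC = 1.00
bend_GG = 1.00
bend_GT = 1.00
bend_TA = 1.00
bend_TC = 0.35
bend_TG = 0.50
bend_TT = 1.00

# a_i b_i
calibration_stop = 16.060306 0.30
calibration_slide = 12.80 8.0
calibration_bend = 12.80 8.0
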