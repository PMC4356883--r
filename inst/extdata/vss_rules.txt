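# Coverage-filtered If-Then regression rules (coverage >= 10) relating the
# predicted skin partition coefficient and MOE-style molecular descriptors to
# human steady-state volume of distribution. THEN values are Vss in L/kg
# (linear scale); read with read_rules(..., units = "linear").
IF logK_skin:plasma <= 0.044 AND SlogP_VSA7 <= 88.002 THEN 0.57 ; coverage = 80
IF logK_skin:plasma <= 0.044 AND SlogP_VSA7 > 88.002 AND ASA- <= 181.026 THEN 0.37 ; coverage = 30
IF logK_skin:plasma <= 0.044 AND SlogP_VSA7 > 88.002 AND ASA- > 181.026 THEN 0.27 ; coverage = 60
IF logK_skin:plasma > 0.044 AND a_ICM <= 1.553 AND fiA <= 0.017 AND PEOE_VSA+0 <= 108.431 AND PEOE_RPC- <= 0.187 THEN 1.66 ; coverage = 13
IF logK_skin:plasma > 0.044 AND a_ICM <= 1.553 AND fiA <= 0.017 AND PEOE_VSA+0 <= 108.431 AND PEOE_RPC- > 0.187 THEN 1.96 ; coverage = 26
IF logK_skin:plasma > 0.044 AND a_ICM <= 1.553 AND fiA <= 0.017 AND PEOE_VSA+0 > 108.431 AND SlogP_VSA4 <= 16.939 THEN 3.14 ; coverage = 20
IF logK_skin:plasma > 0.044 AND a_ICM <= 1.553 AND fiA <= 0.017 AND PEOE_VSA+0 > 108.431 AND SlogP_VSA4 > 16.939 THEN 2.15 ; coverage = 19
IF logK_skin:plasma > 0.044 AND a_ICM > 1.553 THEN 1.10 ; coverage = 100
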