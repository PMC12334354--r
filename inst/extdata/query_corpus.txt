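# Query corpus: one query per line, '#' starts a comment.
# Diagnostic product-ion and precursor patterns
QUERY scaninfo(MS2DATA) WHERE MS2PROD=98.9847:TOLERANCEPPM=50:INTENSITYPERCENT=50
QUERY scaninfo(MS2DATA) WHERE MS2PROD=163.1:TOLERANCEMZ=0.1
QUERY scaninfo(MS2DATA) WHERE MS2PROD=163.1:INTENSITYPERCENT=10
QUERY scaninfo(MS2DATA) WHERE MS2PROD=163.1:INTENSITYVALUE=1000
QUERY scaninfo(MS2DATA) WHERE MS2PROD=163.1:EXCLUDED
QUERY scaninfo(MS2DATA) WHERE MS2PREC=488.1:TOLERANCEPPM=20
QUERY scaninfo(MS2DATA) WHERE MS2NL=162.0528:TOLERANCEMZ=0.05
QUERY scannum(MS2DATA) WHERE MS2PROD=85.0295:TOLERANCEPPM=100 AND MS2PROD=127.0390:TOLERANCEPPM=100
QUERY scansum(MS2DATA) WHERE MS2PROD=204.0867:TOLERANCEMZ=0.02
# Boolean structure and metadata constraints
QUERY scaninfo(MS2DATA) WHERE (MS2PROD=163.1:TOLERANCEMZ=0.1 OR MS2NL=146.0579:TOLERANCEMZ=0.1) AND RTMIN=2 AND RTMAX=15
QUERY scaninfo(MS2DATA) WHERE MS2PREC=488.1 AND CHARGE=2 AND POLARITY=Positive
QUERY scaninfo(MS1DATA) WHERE MS1MZ=391.2843:TOLERANCEPPM=10 AND SCANMIN=5 AND SCANMAX=500
QUERY scaninfo(MS1DATA) WHERE MOBILITY=range(min=1, max=2)
QUERY scaninfo(MS1DATA) WHERE MS1MZ=301.1:MASSDEFECT=massdefect(min=0.1, max=0.2)
QUERY scaninfo(MS1DATA)
QUERY scannum(MS2DATA)
# Variable-anchored isotope / adduct patterns
QUERY scaninfo(MS1DATA) WHERE MS1MZ=X:TOLERANCEPPM=10 AND MS1MZ=X-1.993:TOLERANCEPPM=10:INTENSITYMATCH=0.063:INTENSITYMATCHPERCENT=25 AND MS1MZ=X+1.0034:TOLERANCEPPM=10 AND MS1MZ=X-52.91:TOLERANCEPPM=10
QUERY scaninfo(MS1DATA) WHERE MS1MZ=X AND MS1MZ=X+1.9971:TOLERANCEMZ=0.01
QUERY scaninfo(MS2DATA) WHERE MS2PROD=X:INTENSITYPERCENT=25 AND MS2PROD=X-18.0106:TOLERANCEMZ=0.02
# Mixed-level query: MS2 scans whose linked MS1 scan shows the precursor
QUERY scaninfo(MS2DATA) WHERE MS1MZ=391.2843:TOLERANCEMZ=0.05 AND MS2PROD=163.1:TOLERANCEMZ=0.1
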