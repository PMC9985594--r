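priority,pattern,verdict
10,long term,long_term
20,continuous,long_term
30,repeat dispensing,long_term
40,until review,long_term
50,maintenance,long_term
60,every day indefinitely,long_term
110,then stop,intermittent
120,for [0-9]+ days?,intermittent
130,for (one|two|three|four|five|six|seven|eight|nine|ten) days?,intermittent
140,reducing,intermittent
150,taper,intermittent
160,short course,intermittent
170,rescue pack,intermittent
180,day course,intermittent
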