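part,part_label,lhs,support,confidence,lift,note
A,primary school students,high family cohesion,20.81,88.32,1.22,
A,primary school students,high teacher support; no family structure risk,21.15,88.17,1.22,
A,primary school students,high peer support,24.51,86.63,1.20,
A,primary school students,low family conflict; no family structure risk,26.31,85.24,1.18,
A,primary school students,low family conflict; no family structure risk; no family economic strain,20.03,84.73,1.17,
A,primary school students,high teacher support,27.09,84.22,1.17,
A,primary school students,low family conflict,33.19,83.55,1.16,
A,primary school students,low family conflict; not left-behind children,21.58,83.11,1.15,
A,primary school students,low family conflict; no family economic strain,25.37,83.10,1.15,
A,primary school students,high autonomy support,22.36,82.02,1.14,
B,middle school students,high family cohesion; no family structure risk,21.55,86.79,1.28,
B,middle school students,high family cohesion,24.75,86.14,1.27,
B,middle school students,high peer support; no family structure risk,20.69,86.04,1.27,
B,middle school students,high family cohesion; no family economic strain,20.37,85.29,1.26,
B,middle school students,high peer support,24.36,84.32,1.24,
B,middle school students,high peer support; no family economic strain,20.45,83.97,1.24,
B,middle school students,not left-behind children; low family conflicts,20.37,83.39,1.23,
B,middle school students,low family conflict; no family economic strain,23.03,83.33,1.23,
B,middle school students,low family conflict; no family structure risk,23.58,83.20,1.23,
B,middle school students,low family conflict,28.02,82.53,1.22,
B,middle school students,high autonomy support; no family structure risk,21.86,80.69,1.19,
B,middle school students,high teacher support,24.12,80.47,1.19,
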