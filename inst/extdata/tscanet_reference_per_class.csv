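letter,precision,recall,f1
a,89.70,96.30,92.88
b,88.50,95.80,92.01
c,81.00,100.00,89.50
d,96.00,100.00,97.96
e,88.90,92.30,90.57
f,100.00,95.80,97.85
g,95.80,100.00,97.85
h,95.80,92.00,93.86
i,100.00,88.90,94.12
j,100.00,88.00,93.62
k,100.00,95.50,97.70
l,96.60,93.30,94.92
m,100.00,100.00,100.00
n,93.10,93.10,93.10
o,92.30,96.00,94.11
p,100.00,93.30,96.53
q,91.70,91.70,91.70
r,95.80,85.20,90.19
s,100.00,95.20,97.54
t,96.90,100.00,98.43
u,100.00,100.00,100.00
v,90.00,100.00,94.74
w,93.50,96.70,95.07
x,82.60,86.40,84.46
y,90.90,90.90,90.90
z,100.00,86.40,92.70
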