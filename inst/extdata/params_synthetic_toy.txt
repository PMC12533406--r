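version_tag = synthetic-toy-0.1
[baseline]
3 = -6.299999999999997
4 = -3.899999999999999
5 = -1.500000000000000
6 = 0.899999999999999
7 = 3.299999999999997
8 = 5.699999999999999
9 = 8.100000000000001
10 = 10.500000000000000
11 = 12.899999999999999
12 = 15.300000000000001
13 = 17.699999999999999
14 = 20.099999999999998
15 = 22.500000000000000
16 = 24.899999999999999
17 = 27.299999999999997
18 = 29.699999999999999
19 = 32.100000000000001
20 = 34.500000000000000
21 = 36.899999999999999
22 = 39.299999999999997
23 = 41.699999999999996
24 = 44.099999999999994
25 = 46.500000000000000
26 = 48.899999999999999
27 = 51.299999999999997
28 = 53.700000000000003
29 = 56.099999999999994
30 = 58.500000000000000
31 = 60.899999999999999
32 = 63.299999999999997
33 = 65.699999999999989
34 = 68.099999999999994
35 = 70.500000000000000
36 = 72.900000000000006
37 = 75.299999999999997
38 = 77.699999999999989
39 = 80.099999999999994
40 = 82.500000000000000
41 = 84.900000000000006
42 = 87.299999999999997
43 = 89.699999999999989
44 = 92.099999999999994
45 = 94.500000000000000
46 = 96.900000000000006
47 = 99.299999999999997
48 = 101.699999999999989
49 = 104.099999999999994
50 = 106.500000000000000
51 = 108.900000000000006
52 = 111.299999999999983
53 = 113.699999999999989
54 = 116.099999999999994
55 = 118.500000000000000
56 = 120.900000000000006
57 = 123.299999999999983
58 = 125.699999999999989
59 = 128.099999999999994
60 = 130.500000000000000
[xaa]
A = -2
C = -4
D = -3
E = -3
F = -4
G = -4
H = -4
I = -4
K = -3
L = -4
M = -4
N = -3
O = -1
P = 0
Q = -3
R = -3
S = -2
T = -2
V = -4
W = -4
Y = -4
[yaa]
A = -2.5
C = -4.5
D = -3.0
E = -3.0
F = -4.5
G = -4.5
H = -4.5
I = -4.5
K = -3.0
L = -4.5
M = -4.5
N = -3.0
O = 0.0
P = -1.0
Q = -3.0
R = -3.0
S = -2.5
T = -2.5
V = -4.5
W = -4.5
Y = -4.5
[axial]
K:D = 4.0
R:D = 3.5
K:E = 3.5
R:E = 3.0
K:F = 2.0
R:F = 1.5
D:K = 1.5
[lateral]
K:D = 1.5
R:D = 1.2
K:E = 1.2
R:E = 1.0
[frameshift]
000 = -1
111 = 0
222 = 0
[terminal]
N:G:free = -3
C:G:free = -3
N:K:free = -2
C:K:free = -2
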