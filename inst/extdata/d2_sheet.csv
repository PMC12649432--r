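row,position,letter,dashes
1,1,d,2
1,2,d,2
1,3,p,2
1,4,d,1
1,5,d,2
1,6,d,2
1,7,d,2
1,8,d,2
1,9,p,4
1,10,d,2
1,11,p,4
1,12,d,1
1,13,d,4
1,14,d,2
1,15,p,2
1,16,p,3
1,17,p,2
1,18,d,4
1,19,d,2
1,20,d,2
1,21,d,2
1,22,d,1
1,23,p,4
1,24,p,3
1,25,p,2
1,26,d,2
1,27,d,2
1,28,d,4
1,29,p,4
1,30,d,2
1,31,d,2
1,32,d,3
1,33,d,2
1,34,p,4
1,35,d,2
1,36,p,1
1,37,p,3
1,38,d,2
1,39,d,4
1,40,d,2
1,41,p,1
1,42,d,3
1,43,p,1
1,44,d,3
1,45,d,2
1,46,d,2
1,47,d,2
1,48,d,2
1,49,p,3
1,50,d,2
1,51,p,1
1,52,d,3
1,53,p,1
1,54,d,2
1,55,d,1
1,56,p,3
1,57,d,2
2,1,d,4
2,2,d,2
2,3,d,2
2,4,d,2
2,5,d,2
2,6,d,4
2,7,p,4
2,8,d,1
2,9,d,3
2,10,p,4
2,11,d,2
2,12,d,2
2,13,d,2
2,14,p,4
2,15,p,2
2,16,d,2
2,17,d,4
2,18,d,2
2,19,p,1
2,20,d,2
2,21,d,2
2,22,d,2
2,23,p,1
2,24,p,2
2,25,d,4
2,26,p,4
2,27,d,2
2,28,d,2
2,29,d,2
2,30,d,4
2,31,d,2
2,32,p,3
2,33,p,2
2,34,d,2
2,35,d,3
2,36,d,3
2,37,d,2
2,38,p,3
2,39,p,3
2,40,p,4
2,41,p,4
2,42,d,2
2,43,p,3
2,44,p,2
2,45,d,3
2,46,d,2
2,47,d,2
2,48,p,1
2,49,d,2
2,50,p,3
2,51,d,3
2,52,p,2
2,53,d,2
2,54,d,2
2,55,d,2
2,56,d,3
2,57,d,2
3,1,d,2
3,2,p,2
3,3,p,4
3,4,d,4
3,5,d,3
3,6,p,4
3,7,p,1
3,8,p,4
3,9,d,2
3,10,d,2
3,11,d,2
3,12,p,3
3,13,p,1
3,14,d,2
3,15,d,4
3,16,d,2
3,17,d,2
3,18,d,2
3,19,d,2
3,20,d,3
3,21,d,2
3,22,d,2
3,23,p,3
3,24,d,1
3,25,d,2
3,26,p,3
3,27,d,1
3,28,d,4
3,29,p,3
3,30,d,2
3,31,p,1
3,32,p,1
3,33,p,4
3,34,d,1
3,35,p,3
3,36,d,2
3,37,p,1
3,38,d,4
3,39,d,4
3,40,p,2
3,41,d,2
3,42,d,2
3,43,p,4
3,44,d,1
3,45,d,2
3,46,d,2
3,47,d,2
3,48,p,1
3,49,d,2
3,50,d,2
3,51,p,1
3,52,d,2
3,53,d,2
3,54,d,2
3,55,p,2
3,56,d,2
3,57,d,2
4,1,d,2
4,2,p,1
4,3,d,3
4,4,p,2
4,5,d,2
4,6,d,1
4,7,d,2
4,8,p,4
4,9,p,3
4,10,d,2
4,11,d,2
4,12,d,3
4,13,d,1
4,14,d,1
4,15,p,1
4,16,d,2
4,17,d,2
4,18,d,2
4,19,d,2
4,20,p,4
4,21,d,2
4,22,d,2
4,23,d,2
4,24,p,4
4,25,d,4
4,26,p,3
4,27,p,1
4,28,d,2
4,29,p,4
4,30,p,4
4,31,p,1
4,32,p,2
4,33,d,2
4,34,d,2
4,35,p,1
4,36,d,2
4,37,d,2
4,38,p,2
4,39,p,2
4,40,d,2
4,41,d,2
4,42,d,4
4,43,p,3
4,44,p,4
4,45,d,2
4,46,p,3
4,47,d,2
4,48,d,2
4,49,p,2
4,50,p,1
4,51,d,4
4,52,d,2
4,53,d,1
4,54,d,2
4,55,d,4
4,56,d,2
4,57,d,1
5,1,d,2
5,2,p,4
5,3,p,3
5,4,p,4
5,5,d,2
5,6,d,2
5,7,d,2
5,8,p,4
5,9,p,2
5,10,p,3
5,11,d,2
5,12,d,4
5,13,d,4
5,14,d,2
5,15,p,4
5,16,d,2
5,17,d,2
5,18,d,2
5,19,p,4
5,20,d,2
5,21,d,2
5,22,d,2
5,23,d,3
5,24,p,3
5,25,d,1
5,26,d,2
5,27,d,2
5,28,p,3
5,29,p,4
5,30,d,1
5,31,d,2
5,32,p,4
5,33,p,1
5,34,d,4
5,35,d,2
5,36,p,3
5,37,d,2
5,38,p,1
5,39,p,3
5,40,p,1
5,41,p,2
5,42,p,4
5,43,d,2
5,44,d,2
5,45,d,2
5,46,d,2
5,47,p,4
5,48,d,4
5,49,d,2
5,50,p,2
5,51,p,2
5,52,d,2
5,53,d,2
5,54,d,2
5,55,d,4
5,56,d,1
5,57,d,2
6,1,p,2
6,2,d,2
6,3,p,4
6,4,p,2
6,5,d,2
6,6,d,2
6,7,d,2
6,8,d,2
6,9,d,2
6,10,d,2
6,11,p,2
6,12,p,1
6,13,d,2
6,14,p,4
6,15,p,1
6,16,p,3
6,17,d,2
6,18,d,2
6,19,p,3
6,20,p,3
6,21,p,3
6,22,d,2
6,23,p,3
6,24,d,2
6,25,d,2
6,26,p,2
6,27,p,3
6,28,d,2
6,29,d,4
6,30,d,2
6,31,p,4
6,32,p,4
6,33,d,2
6,34,p,3
6,35,d,2
6,36,p,1
6,37,d,2
6,38,p,4
6,39,p,3
6,40,d,1
6,41,p,3
6,42,d,2
6,43,p,2
6,44,d,3
6,45,p,4
6,46,d,2
6,47,p,3
6,48,d,2
6,49,d,2
6,50,d,2
6,51,p,3
6,52,p,2
6,53,d,4
6,54,p,4
6,55,d,2
6,56,d,2
6,57,d,2
7,1,p,3
7,2,d,2
7,3,d,2
7,4,p,3
7,5,p,3
7,6,d,2
7,7,d,2
7,8,d,2
7,9,d,4
7,10,d,3
7,11,d,2
7,12,d,2
7,13,d,2
7,14,d,2
7,15,p,3
7,16,d,1
7,17,d,2
7,18,d,2
7,19,p,4
7,20,p,3
7,21,d,3
7,22,p,1
7,23,d,4
7,24,d,2
7,25,p,2
7,26,d,1
7,27,d,1
7,28,p,3
7,29,p,4
7,30,p,1
7,31,p,1
7,32,p,3
7,33,d,2
7,34,d,2
7,35,p,4
7,36,p,3
7,37,p,1
7,38,d,2
7,39,d,2
7,40,d,4
7,41,d,2
7,42,p,3
7,43,p,3
7,44,d,4
7,45,p,1
7,46,p,3
7,47,d,2
7,48,d,2
7,49,p,3
7,50,p,2
7,51,d,2
7,52,d,2
7,53,d,2
7,54,d,2
7,55,d,2
7,56,d,2
7,57,p,4
8,1,d,2
8,2,d,2
8,3,p,2
8,4,d,2
8,5,d,2
8,6,p,2
8,7,p,4
8,8,p,2
8,9,d,1
8,10,d,2
8,11,d,4
8,12,d,2
8,13,d,4
8,14,d,2
8,15,d,2
8,16,p,3
8,17,d,4
8,18,d,2
8,19,p,4
8,20,p,3
8,21,d,3
8,22,d,2
8,23,p,3
8,24,d,2
8,25,d,2
8,26,d,2
8,27,d,2
8,28,p,2
8,29,p,1
8,30,p,4
8,31,p,3
8,32,d,2
8,33,d,3
8,34,d,2
8,35,d,2
8,36,d,2
8,37,d,2
8,38,d,3
8,39,p,1
8,40,p,1
8,41,d,2
8,42,d,2
8,43,d,2
8,44,d,4
8,45,p,1
8,46,d,2
8,47,d,2
8,48,p,2
8,49,d,4
8,50,d,2
8,51,p,2
8,52,p,1
8,53,d,2
8,54,p,4
8,55,p,1
8,56,d,3
8,57,d,1
9,1,p,4
9,2,d,1
9,3,p,2
9,4,d,2
9,5,p,2
9,6,d,2
9,7,d,2
9,8,d,1
9,9,p,3
9,10,p,4
9,11,d,2
9,12,p,3
9,13,p,1
9,14,d,4
9,15,d,2
9,16,p,3
9,17,d,2
9,18,p,2
9,19,d,4
9,20,d,2
9,21,d,2
9,22,d,4
9,23,p,2
9,24,d,2
9,25,d,4
9,26,d,2
9,27,d,2
9,28,d,2
9,29,d,3
9,30,d,2
9,31,d,2
9,32,d,2
9,33,p,4
9,34,d,2
9,35,d,2
9,36,d,2
9,37,d,2
9,38,d,4
9,39,d,3
9,40,p,3
9,41,d,2
9,42,d,4
9,43,d,2
9,44,d,2
9,45,d,2
9,46,p,3
9,47,d,3
9,48,p,3
9,49,d,2
9,50,p,3
9,51,p,2
9,52,p,2
9,53,d,4
9,54,d,2
9,55,d,4
9,56,d,3
9,57,d,2
10,1,d,2
10,2,d,2
10,3,d,2
10,4,p,1
10,5,p,3
10,6,d,2
10,7,d,2
10,8,p,4
10,9,d,2
10,10,d,4
10,11,d,3
10,12,p,2
10,13,d,2
10,14,d,2
10,15,d,2
10,16,d,3
10,17,d,2
10,18,d,1
10,19,d,1
10,20,d,3
10,21,d,2
10,22,d,2
10,23,p,2
10,24,d,2
10,25,d,1
10,26,p,4
10,27,d,2
10,28,p,4
10,29,p,2
10,30,d,3
10,31,d,2
10,32,d,1
10,33,d,2
10,34,d,3
10,35,p,2
10,36,p,1
10,37,p,1
10,38,d,2
10,39,p,1
10,40,d,3
10,41,p,2
10,42,d,3
10,43,d,2
10,44,d,2
10,45,d,4
10,46,p,2
10,47,d,2
10,48,d,2
10,49,p,3
10,50,p,2
10,51,p,4
10,52,d,2
10,53,d,2
10,54,p,2
10,55,p,1
10,56,d,2
10,57,d,2
11,1,p,2
11,2,d,1
11,3,d,2
11,4,d,4
11,5,d,4
11,6,p,4
11,7,d,2
11,8,p,3
11,9,d,2
11,10,d,2
11,11,d,1
11,12,d,2
11,13,p,3
11,14,d,2
11,15,d,2
11,16,d,1
11,17,d,2
11,18,p,3
11,19,d,2
11,20,d,2
11,21,d,2
11,22,d,2
11,23,p,2
11,24,p,4
11,25,p,4
11,26,d,2
11,27,p,3
11,28,d,2
11,29,p,3
11,30,d,4
11,31,d,1
11,32,d,1
11,33,d,2
11,34,d,2
11,35,p,4
11,36,d,2
11,37,p,3
11,38,p,4
11,39,p,4
11,40,p,2
11,41,d,2
11,42,p,2
11,43,d,1
11,44,p,1
11,45,d,2
11,46,d,2
11,47,d,2
11,48,d,2
11,49,d,2
11,50,p,4
11,51,p,1
11,52,p,1
11,53,d,2
11,54,d,2
11,55,p,4
11,56,d,2
11,57,p,2
12,1,d,3
12,2,d,2
12,3,p,1
12,4,d,4
12,5,d,2
12,6,d,2
12,7,p,2
12,8,d,2
12,9,d,2
12,10,d,4
12,11,d,3
12,12,p,3
12,13,p,3
12,14,d,4
12,15,p,1
12,16,d,1
12,17,p,1
12,18,d,2
12,19,d,3
12,20,d,2
12,21,d,1
12,22,d,2
12,23,p,4
12,24,p,2
12,25,d,3
12,26,p,4
12,27,d,2
12,28,p,1
12,29,d,2
12,30,p,4
12,31,d,2
12,32,d,4
12,33,p,1
12,34,d,2
12,35,d,2
12,36,p,3
12,37,d,2
12,38,d,2
12,39,d,2
12,40,d,2
12,41,d,2
12,42,d,2
12,43,d,2
12,44,p,3
12,45,d,4
12,46,d,2
12,47,d,1
12,48,d,2
12,49,d,2
12,50,p,4
12,51,d,2
12,52,d,2
12,53,d,1
12,54,d,3
12,55,d,2
12,56,p,1
12,57,d,3
13,1,d,2
13,2,p,2
13,3,d,3
13,4,d,4
13,5,d,2
13,6,d,1
13,7,d,4
13,8,p,1
13,9,d,2
13,10,d,2
13,11,d,2
13,12,p,1
13,13,d,2
13,14,d,2
13,15,d,3
13,16,d,2
13,17,d,3
13,18,p,2
13,19,p,3
13,20,p,1
13,21,d,2
13,22,d,3
13,23,p,3
13,24,d,2
13,25,d,2
13,26,d,4
13,27,d,2
13,28,p,1
13,29,p,1
13,30,d,1
13,31,d,2
13,32,d,4
13,33,d,2
13,34,d,2
13,35,d,4
13,36,d,2
13,37,d,4
13,38,p,1
13,39,d,2
13,40,p,3
13,41,d,1
13,42,d,2
13,43,p,3
13,44,d,1
13,45,d,4
13,46,d,2
13,47,d,2
13,48,d,2
13,49,p,1
13,50,d,2
13,51,d,2
13,52,d,2
13,53,p,1
13,54,d,4
13,55,p,2
13,56,d,4
13,57,d,2
14,1,d,1
14,2,d,1
14,3,d,1
14,4,p,2
14,5,d,2
14,6,p,4
14,7,d,2
14,8,d,4
14,9,d,1
14,10,p,4
14,11,d,2
14,12,p,3
14,13,d,2
14,14,p,1
14,15,p,1
14,16,p,2
14,17,d,2
14,18,d,2
14,19,d,4
14,20,d,2
14,21,d,2
14,22,d,2
14,23,p,2
14,24,d,2
14,25,p,3
14,26,d,1
14,27,p,2
14,28,p,1
14,29,d,2
14,30,d,2
14,31,d,2
14,32,p,1
14,33,d,2
14,34,d,2
14,35,d,3
14,36,d,1
14,37,d,2
14,38,d,1
14,39,d,2
14,40,d,1
14,41,p,2
14,42,d,3
14,43,d,2
14,44,d,2
14,45,d,2
14,46,p,3
14,47,d,2
14,48,d,4
14,49,p,2
14,50,d,2
14,51,d,2
14,52,p,2
14,53,d,2
14,54,p,3
14,55,p,1
14,56,d,2
14,57,d,2
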