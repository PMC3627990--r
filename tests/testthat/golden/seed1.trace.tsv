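# apistrack-trace v1
#bee_id	bee0001
#seed	1140350788
#generator	apistrack-sim v1
#csplus_odor	linalool
#csminus_odor	nonanol
#training_order	BAABABBA
#test_order	ABBA
#iti_s	34
#duration_s	4
#acclimation_s	30
#test_delay_s	300
#shock_duration_s	3
#shock_pulse_rate_hz	1.2
#shock_pulse_width_s	0.2
#shock_voltage	10
#length_cm	14.8
#width_cm	2
#depth_cm	0.6
#n_sensors	26
#sampling_rate_hz	5
t_s	x_cm
0.000	-0.2846
0.200	-0.8538
0.400	-0.8538
0.600	-1.4231
0.800	-1.9923
1.000	-1.9923
1.200	-2.5615
1.400	-3.1308
1.600	-3.1308
1.800	-3.1308
2.000	-3.1308
2.200	-2.5615
2.400	-2.5615
2.600	-1.9923
2.800	-1.4231
3.000	-0.8538
3.200	-0.8538
3.400	-0.2846
3.600	0.2846
3.800	0.2846
4.000	0.8538
4.200	1.4231
4.400	1.4231
4.600	1.9923
4.800	2.5615
5.000	3.1308
5.200	3.1308
5.400	3.1308
5.600	3.1308
5.800	3.1308
6.000	3.1308
6.200	3.1308
6.400	3.1308
6.600	2.5615
6.800	1.9923
7.000	1.9923
7.200	1.4231
7.400	0.8538
7.600	0.8538
7.800	0.2846
8.000	-0.2846
8.200	-0.2846
8.400	-0.8538
8.600	-1.4231
8.800	-1.9923
9.000	-1.9923
9.200	-2.5615
9.400	-3.1308
9.600	-3.1308
9.800	-3.7000
10.000	-3.7000
10.200	-3.7000
10.400	-3.1308
10.600	-2.5615
10.800	-2.5615
11.000	-1.9923
11.200	-1.4231
11.400	-1.4231
11.600	-0.8538
11.800	-0.2846
12.000	0.2846
12.200	0.2846
12.400	0.8538
12.600	1.4231
12.800	1.4231
13.000	1.9923
13.200	2.5615
13.400	2.5615
13.600	3.1308
13.800	3.7000
14.000	4.2692
14.200	4.2692
14.400	4.2692
14.600	4.2692
14.800	4.2692
15.000	4.2692
15.200	4.8385
15.400	4.8385
15.600	4.8385
15.800	5.4077
16.000	5.9769
16.200	5.9769
16.400	6.5462
16.600	6.5462
16.800	6.5462
17.000	6.5462
17.200	6.5462
17.400	6.5462
17.600	6.5462
17.800	6.5462
18.000	6.5462
18.200	6.5462
18.400	6.5462
18.600	6.5462
18.800	6.5462
19.000	6.5462
19.200	6.5462
19.400	5.9769
19.600	5.9769
19.800	5.9769
20.000	5.9769
20.200	5.9769
20.400	5.9769
20.600	5.9769
20.800	5.9769
21.000	5.4077
21.200	5.4077
21.400	5.4077
21.600	5.4077
21.800	4.8385
22.000	4.8385
22.200	4.2692
22.400	3.7000
22.600	3.7000
22.800	3.1308
23.000	2.5615
23.200	2.5615
23.400	1.9923
23.600	1.4231
23.800	0.8538
24.000	0.8538
24.200	0.2846
24.400	-0.2846
24.600	-0.2846
24.800	-0.8538
25.000	-1.4231
25.200	-1.4231
25.400	-1.9923
25.600	-2.5615
25.800	-3.1308
26.000	-3.1308
26.200	-3.7000
26.400	-4.2692
26.600	-4.2692
26.800	-4.8385
27.000	-5.4077
27.200	-5.4077
27.400	-5.4077
27.600	-5.4077
27.800	-5.4077
28.000	-5.4077
28.200	-5.9769
28.400	-6.5462
28.600	-6.5462
28.800	-6.5462
29.000	-6.5462
29.200	-6.5462
29.400	-6.5462
29.600	-5.9769
29.800	-5.4077
30.000	-4.8385
30.200	-4.8385
30.400	-4.2692
30.600	-3.7000
30.800	-3.7000
31.000	-3.1308
31.200	-2.5615
31.400	-1.9923
31.600	-1.9923
31.800	-1.4231
32.000	-0.8538
32.200	-0.8538
32.400	-0.2846
32.600	0.2846
32.800	0.2846
33.000	0.8538
33.200	1.4231
33.400	1.9923
33.600	1.9923
33.800	2.5615
34.000	3.1308
34.200	2.5615
34.400	1.9923
34.600	1.9923
34.800	1.4231
35.000	0.8538
35.200	0.2846
35.400	0.2846
35.600	-0.2846
35.800	-0.8538
36.000	-0.8538
36.200	-1.4231
36.400	-1.9923
36.600	-1.9923
36.800	-2.5615
37.000	-3.1308
37.200	-3.7000
37.400	-3.7000
37.600	-4.2692
37.800	-4.8385
38.000	-4.8385
38.200	-5.4077
38.400	-5.9769
38.600	-6.5462
38.800	-6.5462
39.000	-6.5462
39.200	-6.5462
39.400	-5.9769
39.600	-5.4077
39.800	-5.4077
40.000	-4.8385
40.200	-4.2692
40.400	-4.2692
40.600	-3.7000
40.800	-3.1308
41.000	-3.1308
41.200	-2.5615
41.400	-1.9923
41.600	-1.4231
41.800	-1.4231
42.000	-0.8538
42.200	-0.2846
42.400	-0.2846
42.600	0.2846
42.800	0.8538
43.000	0.8538
43.200	1.4231
43.400	1.9923
43.600	2.5615
43.800	2.5615
44.000	3.1308
44.200	3.7000
44.400	3.7000
44.600	4.2692
44.800	4.8385
45.000	5.4077
45.200	5.4077
45.400	5.4077
45.600	5.4077
45.800	4.8385
46.000	4.8385
46.200	4.2692
46.400	3.7000
46.600	3.1308
46.800	3.1308
47.000	2.5615
47.200	1.9923
47.400	1.9923
47.600	1.4231
47.800	0.8538
48.000	0.8538
48.200	0.2846
48.400	-0.2846
48.600	-0.8538
48.800	-0.8538
49.000	-1.4231
49.200	-1.9923
49.400	-1.9923
49.600	-1.9923
49.800	-1.9923
50.000	-2.5615
50.200	-2.5615
50.400	-3.1308
50.600	-3.7000
50.800	-4.2692
51.000	-4.2692
51.200	-4.8385
51.400	-5.4077
51.600	-5.4077
51.800	-5.9769
52.000	-6.5462
52.200	-6.5462
52.400	-6.5462
52.600	-6.5462
52.800	-6.5462
53.000	-6.5462
53.200	-6.5462
53.400	-5.9769
53.600	-5.4077
53.800	-4.8385
54.000	-4.8385
54.200	-4.2692
54.400	-3.7000
54.600	-3.7000
54.800	-3.1308
55.000	-2.5615
55.200	-2.5615
55.400	-1.9923
55.600	-1.4231
55.800	-0.8538
56.000	-0.8538
56.200	-0.2846
56.400	0.2846
56.600	0.2846
56.800	0.8538
57.000	1.4231
57.200	1.9923
57.400	1.9923
57.600	2.5615
57.800	3.1308
58.000	3.1308
58.200	3.7000
58.400	4.2692
58.600	4.2692
58.800	4.8385
59.000	5.4077
59.200	5.9769
59.400	5.9769
59.600	6.5462
59.800	6.5462
60.000	6.5462
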