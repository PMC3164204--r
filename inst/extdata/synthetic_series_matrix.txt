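!Series_title	"synthetic 10-probe series-matrix style fixture (not real data)"
!Series_platform_id	"SYNTH0"
!Sample_title	"donor-a"	"donor-b"	"iPS-a"	"iPS-b"
!series_matrix_table_begin
ID_REF	donor-a	donor-b	iPS-a	iPS-b	donor-a.Detection	donor-b.Detection	iPS-a.Detection	iPS-b.Detection
P00001	8.12	8.05	8.20	8.31	0.001	0.002	0.001	0.003
P00002	6.44	6.51	9.72	9.60	0.004	0.006	0.001	0.001
P00003	4.02	4.11	4.05	3.98	0.45	0.62	0.51	0.38
P00004	10.21	10.30	6.10	6.02	0.001	0.001	0.74	0.81
P00005	7.33	7.28	7.41	7.35	0.002	0.003	0.005	0.004
P00006	3.95	4.08	9.11	9.05	0.88	0.91	0.001	0.002
P00007	9.54	9.61	9.48	9.57	0.001	0.001	0.002	0.001
P00008	5.12	5.01	5.22	5.09	0.03	0.04	0.02	0.05
P00009	11.02	10.95	11.10	11.04	0.001	0.002	0.001	0.001
P00010	6.87	6.92	4.01	4.12	0.008	0.007	0.55	0.49
!series_matrix_table_end
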