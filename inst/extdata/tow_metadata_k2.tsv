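# Stratified day/night tow fixture. Dates, times and D/N flags follow the
# field campaign; filtered volumes are SYNTHETIC (6 m3 per metre of layer
# thickness) because per-layer flowmeter volumes were not published.
sample_id	date	local_time	day_night	top_m	bottom_m	filtered_volume_m3	aliquot_fraction	mesh_um	mouth_area_m2
Oct_D_L1	2010-10-29	12:09-13:52	D	0	50	300	1/128	335	1.5
Oct_D_L2	2010-10-29	12:09-13:52	D	50	100	300	1/64	335	1.5
Oct_D_L3	2010-10-29	12:09-13:52	D	100	150	300	1/32	335	1.5
Oct_D_L4	2010-10-29	12:09-13:52	D	150	200	300	1/16	335	1.5
Oct_D_L5	2010-10-29	12:09-13:52	D	200	300	600	1/8	335	1.5
Oct_D_L6	2010-10-29	12:09-13:52	D	300	500	1200	1/4	335	1.5
Oct_D_L7	2010-10-29	12:09-13:52	D	500	750	1500	1/2	335	1.5
Oct_D_L8	2010-10-29	12:09-13:52	D	750	1000	1500	1/2	335	1.5
Oct_N_L1	2010-10-29	22:09-23:38	N	0	50	300	1/128	335	1.5
Oct_N_L2	2010-10-29	22:09-23:38	N	50	100	300	1/64	335	1.5
Oct_N_L3	2010-10-29	22:09-23:38	N	100	150	300	1/32	335	1.5
Oct_N_L4	2010-10-29	22:09-23:38	N	150	200	300	1/16	335	1.5
Oct_N_L5	2010-10-29	22:09-23:38	N	200	300	600	1/8	335	1.5
Oct_N_L6	2010-10-29	22:09-23:38	N	300	500	1200	1/4	335	1.5
Oct_N_L7	2010-10-29	22:09-23:38	N	500	750	1500	1/2	335	1.5
Oct_N_L8	2010-10-29	22:09-23:38	N	750	1000	1500	1/2	335	1.5
Feb_D_L1	2011-02-26	12:35-14:41	D	0	50	300	1/32	335	1.5
Feb_D_L2	2011-02-26	12:35-14:41	D	50	100	300	1/16	335	1.5
Feb_D_L3	2011-02-26	12:35-14:41	D	100	150	300	1/16	335	1.5
Feb_D_L4	2011-02-26	12:35-14:41	D	150	200	300	1/8	335	1.5
Feb_D_L5	2011-02-26	12:35-14:41	D	200	300	600	1/8	335	1.5
Feb_D_L6	2011-02-26	12:35-14:41	D	300	500	1200	1/4	335	1.5
Feb_D_L7	2011-02-26	12:35-14:41	D	500	750	1500	1/2	335	1.5
Feb_D_L8	2011-02-26	12:35-14:41	D	750	1000	1500	1/2	335	1.5
Feb_N_L1	2011-02-26	22:01-23:44	N	0	50	300	1/32	335	1.5
Feb_N_L2	2011-02-26	22:01-23:44	N	50	100	300	1/16	335	1.5
Feb_N_L3	2011-02-26	22:01-23:44	N	100	150	300	1/16	335	1.5
Feb_N_L4	2011-02-26	22:01-23:44	N	150	200	300	1/8	335	1.5
Feb_N_L5	2011-02-26	22:01-23:44	N	200	300	600	1/8	335	1.5
Feb_N_L6	2011-02-26	22:01-23:44	N	300	500	1200	1/4	335	1.5
Feb_N_L7	2011-02-26	22:01-23:44	N	500	750	1500	1/2	335	1.5
Feb_N_L8	2011-02-26	22:01-23:44	N	750	1000	1500	1/2	335	1.5
Apr_N_L1	2011-04-22	21:59-23:56	N	0	50	300	1/32	335	1.5
Apr_N_L2	2011-04-22	21:59-23:56	N	50	100	300	1/16	335	1.5
Apr_N_L3	2011-04-22	21:59-23:56	N	100	150	300	1/16	335	1.5
Apr_N_L4	2011-04-22	21:59-23:56	N	150	200	300	1/8	335	1.5
Apr_N_L5	2011-04-22	21:59-23:56	N	200	300	600	1/8	335	1.5
Apr_N_L6	2011-04-22	21:59-23:56	N	300	500	1200	1/4	335	1.5
Apr_N_L7	2011-04-22	21:59-23:56	N	500	750	1500	1/2	335	1.5
Apr_N_L8	2011-04-22	21:59-23:56	N	750	1000	1500	1/2	335	1.5
Apr_D_L1	2011-04-22	12:45-14:37	D	0	50	300	1/32	335	1.5
Apr_D_L2	2011-04-22	12:45-14:37	D	50	100	300	1/16	335	1.5
Apr_D_L3	2011-04-22	12:45-14:37	D	100	150	300	1/16	335	1.5
Apr_D_L4	2011-04-22	12:45-14:37	D	150	200	300	1/8	335	1.5
Apr_D_L5	2011-04-22	12:45-14:37	D	200	300	600	1/8	335	1.5
Apr_D_L6	2011-04-22	12:45-14:37	D	300	500	1200	1/4	335	1.5
Apr_D_L7	2011-04-22	12:45-14:37	D	500	750	1500	1/2	335	1.5
Apr_D_L8	2011-04-22	12:45-14:37	D	750	1000	1500	1/2	335	1.5
Jul_D_L1	2011-07-03	12:05-13:55	D	0	50	300	1/32	335	1.5
Jul_D_L2	2011-07-03	12:05-13:55	D	50	100	300	1/16	335	1.5
Jul_D_L3	2011-07-03	12:05-13:55	D	100	150	300	1/16	335	1.5
Jul_D_L4	2011-07-03	12:05-13:55	D	150	200	300	1/8	335	1.5
Jul_D_L5	2011-07-03	12:05-13:55	D	200	300	600	1/8	335	1.5
Jul_D_L6	2011-07-03	12:05-13:55	D	300	500	1200	1/4	335	1.5
Jul_D_L7	2011-07-03	12:05-13:55	D	500	750	1500	1/2	335	1.5
Jul_D_L8	2011-07-03	12:05-13:55	D	750	1000	1500	1/2	335	1.5
Jul_N_L1	2011-07-04	22:51-0:55	N	0	50	300	1/32	335	1.5
Jul_N_L2	2011-07-04	22:51-0:55	N	50	100	300	1/16	335	1.5
Jul_N_L3	2011-07-04	22:51-0:55	N	100	150	300	1/16	335	1.5
Jul_N_L4	2011-07-04	22:51-0:55	N	150	200	300	1/8	335	1.5
Jul_N_L5	2011-07-04	22:51-0:55	N	200	300	600	1/8	335	1.5
Jul_N_L6	2011-07-04	22:51-0:55	N	300	500	1200	1/4	335	1.5
Jul_N_L7	2011-07-04	22:51-0:55	N	500	750	1500	1/2	335	1.5
Jul_N_L8	2011-07-04	22:51-0:55	N	750	1000	1500	1/2	335	1.5
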