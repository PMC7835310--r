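# Published per-community benchmark values for eleven mockrobiota mock
# communities (16S V4, genus level), with (gcn) and without (raw)
# copy-number correction. Values at printed 4-decimal precision.
community_id	na_frac	other_frac	shannon_mock	shannon_raw	shannon_gcn	richness_mock	richness_raw	rss_raw	rss_gcn	best_fit	excluded
Mock-12	0.0003	0.0461	2.0736	0.3926	0.5765	11	13	1.3138	1.3274	raw	TRUE
Mock-13	0.0005	0.0057	2.8216	2.6968	2.7120	18	32	0.5198	0.5258	raw	FALSE
Mock-14	0.0003	0.0103	2.8216	2.7039	2.7456	18	35	0.5245	0.4991	gcn	FALSE
Mock-15	0.0001	0.0038	2.8216	2.6950	2.6591	18	30	0.5447	0.5823	raw	FALSE
Mock-16	0.0853	0.0913	3.7543	3.1574	3.0887	46	54	0.8441	0.9053	raw	FALSE
Mock-18	0.0019	0.0000	2.7081	2.6027	2.4329	15	15	0.3089	0.5965	raw	FALSE
Mock-19	0.3074	0.0000	2.3581	2.4581	2.1697	15	15	0.8829	1.1353	raw	FALSE
Mock-20	0.0000	0.0001	2.7616	2.5335	2.4519	17	17	0.5107	0.5766	raw	FALSE
Mock-21	0.0000	0.0000	1.6901	1.5246	1.5091	17	14	0.4041	0.3534	gcn	FALSE
Mock-22	0.0004	0.0292	2.7616	2.7212	2.7024	17	20	0.2978	0.4075	raw	FALSE
Mock-23	0.0008	0.0017	1.6901	1.7205	1.7214	17	20	0.1938	0.1566	gcn	FALSE
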