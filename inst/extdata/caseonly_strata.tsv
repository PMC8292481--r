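stratum	noncarrier_counts	carrier_counts	printed_or	printed_ci_low	printed_ci_high	printed_p	note
SWEA1	549–138–16	60–5–2	0.46	0.17	1.04	0.053	carrier GG printed as 0; 60 restored from the stated 67 carriers and printed percentages (90-7-3); printed OR/CI/p not reproduced by either sample or conditional estimator (known discrepancy); noncarrier total 703 vs 688 stated in text
SWEA2	73–14–0	34–11–0	1.68	0.62	4.47	0.25	
Helsinki1—unselected	1432–232–9	44–4–0	0.54	0.14	1.50	0.30	
Helsinki1—additional familial	603–99–3	45–4–1	0.66	0.20	1.71	0.53	
Helsinki2	841–119–5	26–2–0	0.52	0.06	2.13	0.57	printed p 0.57 vs exact Fisher p 0.5649, reachable only by double rounding (0.5649 to 0.565 to 0.57)
Tampere	564–87–1	12–2–0	1.10	0.11	4.92	1.00	printed OR 1.10 vs sample/conditional 1.07 (known discrepancy); CI and p match the exact machinery
Combined	NA	NA	0.69	0.46	1.03	0.073	printed pooled value not reproduced by standard Mantel–Haenszel pooling of the printed triplets (known discrepancy; direct-formula value 0.667)
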