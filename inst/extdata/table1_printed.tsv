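id	test	printed	data	reproducible	note
age_anova	anova_summary	2.057	37.00,33.25,38.65,10.13,7.76,9.34,28,24,20	FALSE	recomputes as 2.058; limited by 2-dp rounding of printed means/SDs
handedness	chi2_3x3	0.207	2,3,23,2,2,20,2,2,16	TRUE	3 groups x left/ambidexter/right, df 4
education_own	none	4.005	NA	FALSE	Kruskal-Wallis on raw scores; only median/IQR printed
education_mother	none	1.325	NA	FALSE	Kruskal-Wallis on raw scores; only median/IQR printed
education_father	none	0.044	NA	FALSE	Kruskal-Wallis on raw scores; only median/IQR printed
time_since_deployment	none	0.218	NA	FALSE	Kruskal-Wallis on raw values; only mean/SD printed
times_deployed	none	0.416	NA	FALSE	printed df 2 inconsistent with the 3x4 count table (df 6); no standard formula matches
fd	none	3.278	NA	FALSE	Kruskal-Wallis on raw values; only mean/SD printed
tiv_t	t_summary	-0.506	1550.02,121.15,24,1528.06,166.44,20	TRUE	responders listed first; sign follows non-responder minus responder
caps_baseline_t	t_summary	0.504	69.85,11.45,20,71.92,15.06,24	TRUE	printed sign requires responder minus non-responder order
mood_pre	chi2_2x2	0.076	13,11,10,10	TRUE	comorbid mood disorder yes/no x responder/non-responder
anxiety_pre	chi2_2x2	2.937	5,19,9,11	TRUE
somatoform_pre	chi2_2x2	0.017	1,23,1,19	TRUE
sri_pre	chi2_2x2	1.104	5,19,7,13	TRUE
benzo_pre	chi2_2x2	1.247	7,17,3,17	TRUE
antipsychotics_pre	chi2_2x2	1.746	2,22,0,20	TRUE
sessions_t	none	-0.114	NA	FALSE	printed df 38 implies unknown per-group n (missing data)
tfcbt	chi2_2x2	2.946	6,18,10,10	TRUE
emdr	chi2_2x2	0.081	20,4,16,4	TRUE
caps_post_t	t_summary	7.889	29.75,16.53,24,68.55,15.89,20	TRUE	responders first; sign follows non-responder minus responder
mood_post	chi2_2x2	0.096	3,21,3,17	FALSE	printed counts give 0.058; denominators at follow-up evidently differ
anxiety_post	chi2_2x2	2.516	2,22,5,15	FALSE	printed counts give 2.265
somatoform_post	chi2_2x2	1.293	0,24,1,19	FALSE	printed counts give 1.228
alcohol_post	chi2_2x2	2.650	0,24,2,18	FALSE	printed counts give 2.514
sri_post	chi2_2x2	5.768	5,19,11,9	FALSE	printed counts give 5.503; no standard variant matches
benzo_post	chi2_2x2	2.307	5,19,1,19	FALSE	printed counts give 2.322
antipsychotics_post	chi2_2x2	0.040	2,22,2,18	FALSE	printed counts give 0.045
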