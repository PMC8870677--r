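# Arm-level summaries of the four randomized Ra-223 trials in mCRPC used to
# build the virtual cohort. One row per treatment subgroup (arm).
# Columns:
#   study_id        study label A-D
#   n_patients      patients in the arm
#   activity_kbq_kg injected Ra-223 activity per cycle, kBq per kg body
#                   weight (0 = placebo)
#   mbq_per_cycle   injected activity per cycle, MBq (as printed; overrides
#                   any weight-based conversion)
#   n_cycles        number of treatment cycles (study D reported "up to 6";
#                   encoded as 6 for all its patients)
#   f_ebrt_pct      percentage of the arm also receiving EBRT (as printed)
#   f_ebrt_n        count of the arm also receiving EBRT
#   os2y_pct/os2y_n two-year overall survival, percent and event count
#   tox_pct/tox_n   grade >=2 neutropenia, percent and event count
#                   (NA = not reported)
#   os_extraction   how 2y-OS was obtained: "text" (reported in the trial
#                   text, no censoring) or "kaplan_meier" (read from
#                   Kaplan-Meier curves, censoring possible)
study_id,n_patients,activity_kbq_kg,mbq_per_cycle,n_cycles,f_ebrt_pct,f_ebrt_n,os2y_pct,os2y_n,tox_pct,tox_n,os_extraction
A,33,50,3.5,4,100,33,30,10,0,0,text
A,31,0,0,0,100,31,13,4,0,0,text
B,41,25,1.75,3,29,12,37,15,0,0,text
B,39,50,3.5,3,44,17,44,17,18,7,text
B,42,80,5.6,3,36,15,48,20,21,9,text
C,614,50,3.5,6,16,98,30,184,5,31,kaplan_meier
C,307,0,0,0,16,49,18,55,1,3,kaplan_meier
D,49,55,4.125,6,29,14,49,24,NA,NA,kaplan_meier
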