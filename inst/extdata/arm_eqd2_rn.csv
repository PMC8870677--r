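# Published per-arm EQD2 of the Ra-223 component (Gy), derived in the source
# analysis from lesion-level spherical-model dosimetry averaged over 24 bone
# lesions. Keyed by (study_id, activity_kbq_kg); used directly for table
# reproduction and as calibration input where the underlying per-nuclide dose
# coefficients are not published.
study_id,activity_kbq_kg,n_cycles,eqd2_rn_gy
A,50,4,103.2
A,0,0,0
B,25,3,34.2
B,50,3,77.4
B,80,3,140.7
C,50,6,154.8
C,0,0,0
D,55,6,174.0
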