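key,value,description
total_subjects,55,all enrolled subjects
patients,48,subjects recruited as patients (incl. HB I after surgery)
healthy_controls,7,healthy controls without cranial surgery
fp_patients,40,patients with facial palsy (HB II-VI)
iatrogenic_fp,37,palsies of iatrogenic etiology
idiopathic_fp,2,palsies of idiopathic etiology
tumor_fp,1,palsies of tumor etiology
fars,8,subjects with facial aberrant reinnervation syndrome
female,35,female subjects
male,20,male subjects
hb_I,15,subjects graded House-Brackmann I
hb_II,8,subjects graded House-Brackmann II
hb_III,21,subjects graded House-Brackmann III
hb_IV,5,subjects graded House-Brackmann IV
hb_V,4,subjects graded House-Brackmann V
hb_VI,2,subjects graded House-Brackmann VI
side_left,29,palsy or surgery on the left side
side_right,19,palsy or surgery on the right side
fp_duration_days_mean,672.27,mean days since palsy onset or surgery
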