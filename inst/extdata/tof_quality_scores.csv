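vessel_category,volunteer,field_strength,score
carotid_siphons,1,7T,3
carotid_siphons,1,3T,4
carotid_siphons,2,7T,3
carotid_siphons,2,3T,3
carotid_siphons,3,7T,3
carotid_siphons,3,3T,3
carotid_siphons,4,7T,3
carotid_siphons,4,3T,3
ophthalmic_arteries,1,7T,3
ophthalmic_arteries,1,3T,4
ophthalmic_arteries,2,7T,4
ophthalmic_arteries,2,3T,3
ophthalmic_arteries,3,7T,1
ophthalmic_arteries,3,3T,1
ophthalmic_arteries,4,7T,1
ophthalmic_arteries,4,3T,3
lenticulostriate_arteries,1,7T,4
lenticulostriate_arteries,1,3T,3
lenticulostriate_arteries,2,7T,4
lenticulostriate_arteries,2,3T,2
lenticulostriate_arteries,3,7T,4
lenticulostriate_arteries,3,3T,3
lenticulostriate_arteries,4,7T,4
lenticulostriate_arteries,4,3T,3
anterior_choroidal_arteries,1,7T,3
anterior_choroidal_arteries,1,3T,3
anterior_choroidal_arteries,2,7T,3
anterior_choroidal_arteries,2,3T,3
anterior_choroidal_arteries,3,7T,3
anterior_choroidal_arteries,3,3T,3
anterior_choroidal_arteries,4,7T,3
anterior_choroidal_arteries,4,3T,2
thalamic_perforating_arteries,1,7T,4
thalamic_perforating_arteries,1,3T,2
thalamic_perforating_arteries,2,7T,3
thalamic_perforating_arteries,2,3T,0
thalamic_perforating_arteries,3,7T,2
thalamic_perforating_arteries,3,3T,0
thalamic_perforating_arteries,4,7T,3
thalamic_perforating_arteries,4,3T,0
pontine_perforating_arteries,1,7T,0
pontine_perforating_arteries,1,3T,0
pontine_perforating_arteries,2,7T,2
pontine_perforating_arteries,2,3T,0
pontine_perforating_arteries,3,7T,1
pontine_perforating_arteries,3,3T,0
pontine_perforating_arteries,4,7T,1
pontine_perforating_arteries,4,3T,0
cerebral_arteries,1,7T,4
cerebral_arteries,1,3T,4
cerebral_arteries,2,7T,4
cerebral_arteries,2,3T,4
cerebral_arteries,3,7T,4
cerebral_arteries,3,3T,4
cerebral_arteries,4,7T,4
cerebral_arteries,4,3T,4
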