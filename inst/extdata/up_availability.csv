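# Survey-based availability of cancer-control staff, beds and radiotherapy
# equipment for Uttar Pradesh and its ten cities with radiotherapy centres
# (2013 telephone survey plus institutional websites). flag=nonexistent
# marks specializations that do not exist locally (count necessarily 0).
# Gastro-surgeons are surveyed separately; analyses may pool them with
# surgical oncologists via merge_available_categories().
geography,category,count,flag
Uttar Pradesh,hematologist_oncologists,7,
Uttar Pradesh,surgical_oncologists,21,
Uttar Pradesh,gastro_surgeons,21,
Uttar Pradesh,radiation_clinical_oncologists,87,
Uttar Pradesh,urologic_oncologists,20,
Uttar Pradesh,gynecologic_oncologists,24,
Uttar Pradesh,neurologic_oncologists,26,
Uttar Pradesh,pathologists,179,
Uttar Pradesh,palliative_care_specialists,8,
Uttar Pradesh,oncology_nurses,233,
Uttar Pradesh,oncopharmacists,0,nonexistent
Uttar Pradesh,pharmacy_technicians,0,nonexistent
Uttar Pradesh,beds,875,
Uttar Pradesh,rt_technicians,83,
Uttar Pradesh,medical_physicists,38,
Uttar Pradesh,linac_engineers,0,nonexistent
Uttar Pradesh,rt_nurses,0,nonexistent
Uttar Pradesh,teletherapy,26,
Uttar Pradesh,brachytherapy,17,
Uttar Pradesh,ct_simulator,11,
Uttar Pradesh,tps,19,
Uttar Pradesh,dosimetry_qa,0,
Agra,hematologist_oncologists,0,
Agra,surgical_oncologists,0,
Agra,radiation_clinical_oncologists,4,
Agra,urologic_oncologists,0,
Agra,gynecologic_oncologists,2,
Agra,neurologic_oncologists,2,
Agra,pathologists,11,
Agra,palliative_care_specialists,0,
Agra,oncology_nurses,10,
Agra,oncopharmacists,0,nonexistent
Agra,pharmacy_technicians,0,nonexistent
Agra,beds,50,
Agra,rt_technicians,5,
Agra,medical_physicists,2,
Agra,linac_engineers,0,nonexistent
Agra,rt_nurses,0,nonexistent
Agra,teletherapy,1,
Agra,brachytherapy,1,
Agra,ct_simulator,0,
Agra,tps,1,
Agra,dosimetry_qa,0,
Aligarh,hematologist_oncologists,0,
Aligarh,surgical_oncologists,0,
Aligarh,radiation_clinical_oncologists,3,
Aligarh,urologic_oncologists,0,
Aligarh,gynecologic_oncologists,2,
Aligarh,neurologic_oncologists,0,
Aligarh,pathologists,16,
Aligarh,palliative_care_specialists,0,
Aligarh,oncology_nurses,7,
Aligarh,oncopharmacists,0,nonexistent
Aligarh,pharmacy_technicians,0,nonexistent
Aligarh,beds,35,
Aligarh,rt_technicians,2,
Aligarh,medical_physicists,1,
Aligarh,linac_engineers,0,nonexistent
Aligarh,rt_nurses,0,nonexistent
Aligarh,teletherapy,1,
Aligarh,brachytherapy,1,
Aligarh,ct_simulator,0,
Aligarh,tps,1,
Aligarh,dosimetry_qa,0,
Allahabad,hematologist_oncologists,1,
Allahabad,surgical_oncologists,1,
Allahabad,radiation_clinical_oncologists,9,
Allahabad,urologic_oncologists,1,
Allahabad,gynecologic_oncologists,2,
Allahabad,neurologic_oncologists,2,
Allahabad,pathologists,25,
Allahabad,palliative_care_specialists,0,
Allahabad,oncology_nurses,13,
Allahabad,oncopharmacists,0,nonexistent
Allahabad,pharmacy_technicians,0,nonexistent
Allahabad,beds,90,
Allahabad,rt_technicians,11,
Allahabad,medical_physicists,5,
Allahabad,linac_engineers,0,nonexistent
Allahabad,rt_nurses,0,nonexistent
Allahabad,teletherapy,3,
Allahabad,brachytherapy,2,
Allahabad,ct_simulator,2,
Allahabad,tps,2,
Allahabad,dosimetry_qa,0,
Bareilly,hematologist_oncologists,0,
Bareilly,surgical_oncologists,1,
Bareilly,radiation_clinical_oncologists,6,
Bareilly,urologic_oncologists,0,
Bareilly,gynecologic_oncologists,2,
Bareilly,neurologic_oncologists,1,
Bareilly,pathologists,15,
Bareilly,palliative_care_specialists,0,
Bareilly,oncology_nurses,10,
Bareilly,oncopharmacists,0,nonexistent
Bareilly,pharmacy_technicians,0,nonexistent
Bareilly,beds,50,
Bareilly,rt_technicians,5,
Bareilly,medical_physicists,3,
Bareilly,linac_engineers,0,nonexistent
Bareilly,rt_nurses,0,nonexistent
Bareilly,teletherapy,2,
Bareilly,brachytherapy,1,
Bareilly,ct_simulator,1,
Bareilly,tps,1,
Bareilly,dosimetry_qa,0,
Benares,hematologist_oncologists,1,
Benares,surgical_oncologists,5,
Benares,radiation_clinical_oncologists,9,
Benares,urologic_oncologists,4,
Benares,gynecologic_oncologists,2,
Benares,neurologic_oncologists,4,
Benares,pathologists,15,
Benares,palliative_care_specialists,2,
Benares,oncology_nurses,20,
Benares,oncopharmacists,0,nonexistent
Benares,pharmacy_technicians,0,nonexistent
Benares,beds,100,
Benares,rt_technicians,12,
Benares,medical_physicists,4,
Benares,linac_engineers,0,nonexistent
Benares,rt_nurses,0,nonexistent
Benares,teletherapy,4,
Benares,brachytherapy,2,
Benares,ct_simulator,1,
Benares,tps,2,
Benares,dosimetry_qa,0,
Gorakhpur,hematologist_oncologists,0,
Gorakhpur,surgical_oncologists,1,
Gorakhpur,radiation_clinical_oncologists,5,
Gorakhpur,urologic_oncologists,0,
Gorakhpur,gynecologic_oncologists,3,
Gorakhpur,neurologic_oncologists,2,
Gorakhpur,pathologists,16,
Gorakhpur,palliative_care_specialists,0,
Gorakhpur,oncology_nurses,15,
Gorakhpur,oncopharmacists,0,nonexistent
Gorakhpur,pharmacy_technicians,0,nonexistent
Gorakhpur,beds,85,
Gorakhpur,rt_technicians,6,
Gorakhpur,medical_physicists,2,
Gorakhpur,linac_engineers,0,nonexistent
Gorakhpur,rt_nurses,0,nonexistent
Gorakhpur,teletherapy,2,
Gorakhpur,brachytherapy,1,
Gorakhpur,ct_simulator,0,
Gorakhpur,tps,1,
Gorakhpur,dosimetry_qa,0,
Jhansi,hematologist_oncologists,0,
Jhansi,surgical_oncologists,0,
Jhansi,radiation_clinical_oncologists,2,
Jhansi,urologic_oncologists,0,
Jhansi,gynecologic_oncologists,2,
Jhansi,neurologic_oncologists,0,
Jhansi,pathologists,16,
Jhansi,palliative_care_specialists,0,
Jhansi,oncology_nurses,8,
Jhansi,oncopharmacists,0,nonexistent
Jhansi,pharmacy_technicians,0,nonexistent
Jhansi,beds,40,
Jhansi,rt_technicians,2,
Jhansi,medical_physicists,1,
Jhansi,linac_engineers,0,nonexistent
Jhansi,rt_nurses,0,nonexistent
Jhansi,teletherapy,1,
Jhansi,brachytherapy,0,
Jhansi,ct_simulator,0,
Jhansi,tps,0,
Jhansi,dosimetry_qa,0,
Kanpur,hematologist_oncologists,0,
Kanpur,surgical_oncologists,1,
Kanpur,radiation_clinical_oncologists,10,
Kanpur,urologic_oncologists,1,
Kanpur,gynecologic_oncologists,2,
Kanpur,neurologic_oncologists,3,
Kanpur,pathologists,15,
Kanpur,palliative_care_specialists,0,
Kanpur,oncology_nurses,50,
Kanpur,oncopharmacists,0,nonexistent
Kanpur,pharmacy_technicians,0,nonexistent
Kanpur,beds,150,
Kanpur,rt_technicians,8,
Kanpur,medical_physicists,3,
Kanpur,linac_engineers,0,nonexistent
Kanpur,rt_nurses,0,nonexistent
Kanpur,teletherapy,3,
Kanpur,brachytherapy,2,
Kanpur,ct_simulator,2,
Kanpur,tps,2,
Kanpur,dosimetry_qa,0,
Lucknow,hematologist_oncologists,3,
Lucknow,surgical_oncologists,6,
Lucknow,radiation_clinical_oncologists,28,
Lucknow,urologic_oncologists,10,
Lucknow,gynecologic_oncologists,4,
Lucknow,neurologic_oncologists,10,
Lucknow,pathologists,37,
Lucknow,palliative_care_specialists,5,
Lucknow,oncology_nurses,75,
Lucknow,oncopharmacists,0,nonexistent
Lucknow,pharmacy_technicians,0,nonexistent
Lucknow,beds,175,
Lucknow,rt_technicians,20,
Lucknow,medical_physicists,11,
Lucknow,linac_engineers,0,nonexistent
Lucknow,rt_nurses,0,nonexistent
Lucknow,teletherapy,6,
Lucknow,brachytherapy,5,
Lucknow,ct_simulator,3,
Lucknow,tps,6,
Lucknow,dosimetry_qa,0,
Noida,hematologist_oncologists,2,
Noida,surgical_oncologists,6,
Noida,radiation_clinical_oncologists,11,
Noida,urologic_oncologists,4,
Noida,gynecologic_oncologists,3,
Noida,neurologic_oncologists,2,
Noida,pathologists,13,
Noida,palliative_care_specialists,1,
Noida,oncology_nurses,25,
Noida,oncopharmacists,0,nonexistent
Noida,pharmacy_technicians,0,nonexistent
Noida,beds,100,
Noida,rt_technicians,12,
Noida,medical_physicists,6,
Noida,linac_engineers,0,nonexistent
Noida,rt_nurses,0,nonexistent
Noida,teletherapy,3,
Noida,brachytherapy,2,
Noida,ct_simulator,2,
Noida,tps,3,
Noida,dosimetry_qa,0,
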