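parcel_label,system
lh.G_and_S_frontomargin,other
lh.G_and_S_occipital_inf,core
lh.G_and_S_paracentral,extended
lh.G_and_S_subcentral,extended
lh.G_and_S_transv_frontopol,other
lh.G_and_S_cingul-Ant,other
lh.G_and_S_cingul-Mid-Ant,other
lh.G_and_S_cingul-Mid-Post,other
lh.G_cingul-Post-dorsal,other
lh.G_cingul-Post-ventral,other
lh.G_cuneus,other
lh.G_front_inf-Opercular,extended
lh.G_front_inf-Orbital,extended
lh.G_front_inf-Triangul,extended
lh.G_front_middle,other
lh.G_front_sup,extended
lh.G_Ins_lg_and_S_cent_ins,extended
lh.G_insular_short,extended
lh.G_occipital_middle,other
lh.G_occipital_sup,other
lh.G_oc-temp_lat-fusifor,core
lh.G_oc-temp_med-Lingual,other
lh.G_oc-temp_med-Parahip,other
lh.G_orbital,other
lh.G_pariet_inf-Angular,other
lh.G_pariet_inf-Supramar,other
lh.G_parietal_sup,other
lh.G_postcentral,other
lh.G_precentral,other
lh.G_precuneus,other
lh.G_rectus,other
lh.G_subcallosal,other
lh.G_temp_sup-G_T_transv,other
lh.G_temp_sup-Lateral,other
lh.G_temp_sup-Plan_polar,other
lh.G_temp_sup-Plan_tempo,other
lh.G_temporal_inf,other
lh.G_temporal_middle,other
lh.Lat_Fis-ant-Horizont,other
lh.Lat_Fis-ant-Vertical,other
lh.Lat_Fis-post,other
lh.Pole_occipital,other
lh.Pole_temporal,extended
lh.S_calcarine,other
lh.S_central,other
lh.S_cingul-Marginalis,other
lh.S_circular_insula_ant,other
lh.S_circular_insula_inf,other
lh.S_circular_insula_sup,other
lh.S_collat_transv_ant,other
lh.S_collat_transv_post,other
lh.S_front_inf,other
lh.S_front_middle,other
lh.S_front_sup,other
lh.S_interm_prim-Jensen,other
lh.S_intrapariet_and_P_trans,other
lh.S_oc_middle_and_Lunatus,other
lh.S_oc_sup_and_transversal,other
lh.S_occipital_ant,other
lh.S_oc-temp_lat,other
lh.S_oc-temp_med_and_Lingual,other
lh.S_orbital_lateral,other
lh.S_orbital_med-olfact,other
lh.S_orbital-H_Shaped,other
lh.S_parieto_occipital,other
lh.S_pericallosal,other
lh.S_postcentral,other
lh.S_precentral-inf-part,other
lh.S_precentral-sup-part,other
lh.S_suborbital,other
lh.S_subparietal,other
lh.S_temporal_inf,other
lh.S_temporal_sup,core
lh.S_temporal_transverse,other
rh.G_and_S_frontomargin,other
rh.G_and_S_occipital_inf,core
rh.G_and_S_paracentral,extended
rh.G_and_S_subcentral,extended
rh.G_and_S_transv_frontopol,other
rh.G_and_S_cingul-Ant,other
rh.G_and_S_cingul-Mid-Ant,other
rh.G_and_S_cingul-Mid-Post,other
rh.G_cingul-Post-dorsal,other
rh.G_cingul-Post-ventral,other
rh.G_cuneus,other
rh.G_front_inf-Opercular,extended
rh.G_front_inf-Orbital,extended
rh.G_front_inf-Triangul,extended
rh.G_front_middle,other
rh.G_front_sup,extended
rh.G_Ins_lg_and_S_cent_ins,extended
rh.G_insular_short,extended
rh.G_occipital_middle,other
rh.G_occipital_sup,other
rh.G_oc-temp_lat-fusifor,core
rh.G_oc-temp_med-Lingual,other
rh.G_oc-temp_med-Parahip,other
rh.G_orbital,other
rh.G_pariet_inf-Angular,other
rh.G_pariet_inf-Supramar,other
rh.G_parietal_sup,other
rh.G_postcentral,other
rh.G_precentral,other
rh.G_precuneus,other
rh.G_rectus,other
rh.G_subcallosal,other
rh.G_temp_sup-G_T_transv,other
rh.G_temp_sup-Lateral,other
rh.G_temp_sup-Plan_polar,other
rh.G_temp_sup-Plan_tempo,other
rh.G_temporal_inf,other
rh.G_temporal_middle,other
rh.Lat_Fis-ant-Horizont,other
rh.Lat_Fis-ant-Vertical,other
rh.Lat_Fis-post,other
rh.Pole_occipital,other
rh.Pole_temporal,extended
rh.S_calcarine,other
rh.S_central,other
rh.S_cingul-Marginalis,other
rh.S_circular_insula_ant,other
rh.S_circular_insula_inf,other
rh.S_circular_insula_sup,other
rh.S_collat_transv_ant,other
rh.S_collat_transv_post,other
rh.S_front_inf,other
rh.S_front_middle,other
rh.S_front_sup,other
rh.S_interm_prim-Jensen,other
rh.S_intrapariet_and_P_trans,other
rh.S_oc_middle_and_Lunatus,other
rh.S_oc_sup_and_transversal,other
rh.S_occipital_ant,other
rh.S_oc-temp_lat,other
rh.S_oc-temp_med_and_Lingual,other
rh.S_orbital_lateral,other
rh.S_orbital_med-olfact,other
rh.S_orbital-H_Shaped,other
rh.S_parieto_occipital,other
rh.S_pericallosal,other
rh.S_postcentral,other
rh.S_precentral-inf-part,other
rh.S_precentral-sup-part,other
rh.S_suborbital,other
rh.S_subparietal,other
rh.S_temporal_inf,other
rh.S_temporal_sup,core
rh.S_temporal_transverse,other
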