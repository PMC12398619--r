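# Approximate centroid MNI coordinates (mm) of AAL regions used as network
# nodes. Values are rounded centroids from AAL atlas documentation; edit or
# replace with genuine volumetric labels for higher fidelity.
roi,network,aal_label,x_mm,y_mm,z_mm,radius_mm
mPFC,DMN,Frontal_Sup_Medial_L,-5,49,31,10
mPFC,DMN,Frontal_Sup_Medial_R,9,51,30,10
PCC,DMN,Cingulum_Post_L,-5,-43,25,10
PCC,DMN,Cingulum_Post_R,7,-42,22,10
angular,DMN,Angular_L,-44,-61,36,10
angular,DMN,Angular_R,46,-60,39,10
DLPFC,ECN,Frontal_Mid_L,-33,33,35,10
DLPFC,ECN,Frontal_Mid_R,38,33,34,10
PPC,ECN,Parietal_Inf_L,-43,-46,47,10
PPC,ECN,Parietal_Inf_R,46,-46,50,10
ACC,SN,Cingulum_Ant_L,-4,35,14,10
ACC,SN,Cingulum_Ant_R,8,37,16,10
insula,SN,Insula_L,-35,7,3,10
insula,SN,Insula_R,39,6,2,10
amygdala,SN,Amygdala_L,-23,-1,-17,10
amygdala,SN,Amygdala_R,27,1,-18,10
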