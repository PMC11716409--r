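dataset_id,name,field,data_type,disease,repository,references
D1,Mesothelioma Turkey,medical informatics,EHRs,mesothelioma,UC Irvine ML Repo,Er et al. 2012
D2,IBD Paris,medical informatics,EHRs,"IBD, IHD, and CVAD",Figshare,Le Gall et al. 2017; Le Gall et al. 2017 (Figshare)
D3,MIMIC-III,medical informatics,EHRs,critical care,PhysioNet,Johnson et al. 2016; Johnson et al. 2016 (PhysioNet)
D4,Paquid,medical informatics,EHRs,dementia,CRAN,Proust-Lima et al. 2017; Letenneur et al. 1994
D5,GSE16476,bioinformatics,microarray gene expression,neuroblastoma,GEO,Molenaar et al. 2012; GEO GSE16476
D6,E-MTAB-8248,bioinformatics,microarray gene expression,neuroblastoma,ArrayExpress,Bell et al. 2019; ArrayExpress E-MTAB-8248
D7,GSE79209,bioinformatics,bulk RNA-seq gene expression,lung cancer,GEO,Beane et al. 2017; GEO GSE79209
D8,EEG Motor Movement/Imagery,physiologic signals,brain EEG,neurologic conditions,PhysioNet,Schalk et al. 2004; PhysioNet eegmmidb
D9,MIT-BIH ECG Arrhythmia,physiologic signals,heart ECG,arrhythmia,PhysioNet,Moody & Mark 2001; PhysioNet mitdb
D10,Breast Cancer Screening DBT,digital pathology,medical images,breast cancer,TCIA,Buda et al. 2021; TCIA Breast-Cancer-Screening-DBT
D11,DREAM Drug Synergy Challenge,cheminformatics,pharmacology and molecular data,multiple cancers,DREAM Challenges / Synapse,Menden et al. 2019; Synapse syn4231880
D12,MedQuad,NLP,text,multiple diseases,GitHub,Ben Abacha & Demner-Fushman 2019; GitHub MedQuAD
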