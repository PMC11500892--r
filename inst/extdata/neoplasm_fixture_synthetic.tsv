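code	preferred_name	synonyms	parents
C3262	Neoplasm	Tumor|Neoplasms|Tumors	
C9305	Malignant Neoplasm	Cancer|Malignancy|Malignant Tumor	C3262
C9292	Solid Neoplasm	Solid Tumor|Solid Tumors|Advanced Solid Tumor|Advanced Solid Tumors	C9305
C14174	Metastatic Neoplasm	Metastatic Tumor|Metastatic Cancer	C9305
C3677	Benign Neoplasm	Benign Tumor	C3262
C2916	Carcinoma		C9305|C9292
C2852	Adenocarcinoma		C2916
C4878	Lung Carcinoma	Lung Cancer|Carcinoma of the Lung	C2916
C2926	Lung Non-Small Cell Carcinoma	Non-Small Cell Lung Cancer|NSCLC|Non-Small Cell Lung Carcinoma	C4878
C4917	Lung Small Cell Carcinoma	Small Cell Lung Cancer|SCLC	C4878
C3512	Lung Adenocarcinoma	Adenocarcinoma of the Lung|Adenocarcinoma of Lung	C2926|C2852
C2678	Mucinous Adenocarcinoma	Colloid Adenocarcinoma	C2852
C4872	Breast Carcinoma	Breast Cancer|Carcinoma of the Breast	C2916
C5214	Breast Adenocarcinoma	Adenocarcinoma of the Breast	C4872|C2852
C4908	Ovarian Carcinoma	Ovarian Cancer|Carcinoma of the Ovary	C2916
C7700	Ovarian Serous Adenocarcinoma	Serous Ovarian Cancer	C4908|C2852
C2955	Colorectal Carcinoma	Colorectal Cancer	C2916
C5105	Colorectal Adenocarcinoma	Colon Adenocarcinoma|Rectal Adenocarcinoma	C2955|C2852
C3850	Pancreatic Carcinoma	Pancreas Carcinoma	C2916
C8294	Pancreatic Adenocarcinoma	Pancreatic Cancer|Adenocarcinoma of the Pancreas	C3850|C2852
C4863	Prostate Carcinoma	Prostate Cancer	C2916
C2919	Prostate Adenocarcinoma	Adenocarcinoma of the Prostate	C4863|C2852
C4911	Gastric Carcinoma	Stomach Cancer|Gastric Cancer	C2916
C4004	Gastric Adenocarcinoma	Stomach Adenocarcinoma	C4911|C2852
C3099	Hepatocellular Carcinoma	Liver Cell Carcinoma|HCC|Hepatoma	C2916
C9385	Renal Cell Carcinoma	RCC|Kidney Cancer	C2916
C2929	Squamous Cell Carcinoma	Epidermoid Carcinoma	C2916
C34447	Head and Neck Squamous Cell Carcinoma	HNSCC	C2929
C4030	Esophageal Carcinoma	Esophageal Cancer	C2916
C4912	Urothelial Carcinoma	Transitional Cell Carcinoma|Bladder Cancer	C2916
C2915	Endometrial Carcinoma	Endometrial Cancer	C2916
C3224	Melanoma	Malignant Melanoma	C9305|C9292
C3510	Cutaneous Melanoma	Melanoma of the Skin|Skin Melanoma	C3224
C7712	Uveal Melanoma	Ocular Melanoma	C3224
C9306	Sarcoma	Malignant Mesenchymal Neoplasm	C9305|C9292
C9145	Osteosarcoma	Osteogenic Sarcoma	C9306
C3158	Leiomyosarcoma	LMS	C9306
C3194	Liposarcoma		C9306
C3697	Atypical Lipomatous Tumor	ALT|Well Differentiated Liposarcoma	C3194
C4817	Ewing Sarcoma	EWS	C9306
C3234	Mesothelioma	Malignant Mesothelioma	C9305|C9292
C3809	Neuroendocrine Tumor	NET|Neuroendocrine Neoplasm	C9305
C3059	Glioma		C9305
C3058	Glioblastoma	GBM|Glioblastoma Multiforme	C3059
C27134	Hematopoietic and Lymphoid Cell Neoplasm	Hematologic Malignancy	C9305
C3208	Lymphoma		C27134
C9357	Hodgkin Lymphoma	Hodgkin Disease	C3208
C8851	Diffuse Large B-Cell Lymphoma	DLBCL	C3208
C3161	Leukemia		C27134
C3171	Acute Myeloid Leukemia	AML|Acute Myelogenous Leukemia	C3161
C3163	Chronic Lymphocytic Leukemia	CLL	C3161
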