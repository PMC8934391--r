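tissue	normalized_counts
ADRENAL_GLAND	120004
BLADDER	127655
BREAST	44534
CEREBELLUM	124302
CEREBRAL_CORTEX	137064
CEREBRAL_WHITE_MATTER	424818
COLON_TRANSVERSE	75749
DIAPHRAGM	381206
DUODENUM	619992
GALLBLADDER	15953357
ILEUM	1615212
JEJUNUM	284800
KIDNEY	139955
LARYNX	958023
LEFT_HEART	22264
LIVER	530800
LOWER_ESOPHAGUS	58251
LUNG	66785
MONO	11612
PANCREAS	187907
PBMC	6166
PROSTATE	64484
RBC	490
RIGHT_HEART	22535
SCIATIC	393225
SIGMOID_COLON	114936
SKELETAL_MUSCLE	34388
SKIN	136642
SPINAL_CORD	164628
STOMACH	164674
SUBMANDIBULAR_GLAND	37790
THYROID	146499
UPPER_ESOPHAGUS	121985
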