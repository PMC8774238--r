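stage,label,count
report,extra-axial tumors,54
report,infratentorial tumors,60
report,intraventricular tumors,5
report,multiple intra-axial tumors,68
record,benign or infectious/inflammatory lesions,58
record,circumscript or low-grade gliomas,29
record,no final histopathological result,35
record,recurrences of malignant lesions,54
review,non-enhanced CT scans,71
review,post-operative control studies,186
review,tumor affected by artifacts,9
review,peritumoral zone under 10 mm,21
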