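disease,kw1,kw2,kw3,kw4,kw5,kw6,kw7,kw8,regex,mesh
urothelial,urothelial cancer,bladder cancer,ureteral cancer,,,,,,,Urinary Bladder Neoplasms
gastric,gastric cancer,stomach cancer,,,,,,,gastric.{1,100}cancer,Stomach Neoplasms
cervical,cervical cancer,cancer of the cervix,,,,,,,,Uterine Cervical Neoplasms
breast,breast cancer,,,,,,,,breast.{1,100}cancer,Breast Neoplasms
lung,lung cancer,non-small cell lung,small cell lung cancer,,,,,,,Lung Neoplasms
melanoma,melanoma,,,,,,,,,Melanoma
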