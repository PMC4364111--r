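synonym,canonical
Barnes-Jewish Hospital,Barnes-Jewish Hospital
Alvin J. Siteman Cancer Center,Barnes-Jewish Hospital
Washington University,Barnes-Jewish Hospital
Washington University School of Medicine,Barnes-Jewish Hospital
University of Washington,University of Washington Medical Center
University of Washington Medical Center,University of Washington Medical Center
Fred Hutchinson Cancer Research Center,University of Washington Medical Center
Seattle Cancer Care Alliance,University of Washington Medical Center
M.D. Anderson Cancer Center,University of Texas MD Anderson Cancer Center
MD Anderson Cancer Center,University of Texas MD Anderson Cancer Center
University of Texas M.D. Anderson Cancer Center,University of Texas MD Anderson Cancer Center
Memorial Sloan-Kettering Cancer Center,Memorial Sloan-Kettering Cancer Center
Memorial Sloan Kettering Cancer Center,Memorial Sloan-Kettering Cancer Center
MSKCC,Memorial Sloan-Kettering Cancer Center
Dana-Farber Cancer Institute,Dana-Farber/Brigham and Women's Cancer Center
Brigham and Women's Hospital,Dana-Farber/Brigham and Women's Cancer Center
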