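institution,score,sif,registrations
University of Texas MD Anderson Cancer Center,100.00,2362.20,232
Memorial Sloan-Kettering Cancer Center,54.47,1168.19,138
Dana-Farber/Brigham and Women's Cancer Center,45.71,1009.09,113
Massachusetts General Hospital,26.98,562.10,70
Johns Hopkins Hospital,24.11,436.31,69
University of Washington Medical Center,20.79,208.45,76
New York-Presbyterian University Hospital of Columbia and Cornell,19.21,561.18,34
Duke University Medical Center,17.86,416.27,42
Mayo Clinic Rochester,17.02,539.51,26
University of Michigan Hospitals and Health Centers,15.94,284.78,46
Moffitt Cancer Center,15.27,273.38,44
Ohio State University James Cancer Hospital,15.15,400.13,31
Barnes-Jewish Hospital/Washington University,14.92,368.93,33
UPMC-University of Pittsburgh Medical Center,13.91,290.47,36
Stanford Hospital and Clinics,13.54,181.49,45
Emory University Hospital,12.00,210.44,35
UCSF Medical Center,11.69,165.18,38
Roswell Park Cancer Institute,10.39,144.58,34
UCLA Medical Center,9.96,165.09,30
Northwestern Memorial Hospital,9.77,176.54,28
University of North Carolina Hospitals,9.61,250.36,20
University of Minnesota Medical Center,9.58,238.69,21
University of Wisconsin Hospital and Clinics,9.49,81.76,36
University of Chicago Medical Center,8.91,146.23,27
Vanderbilt University Medical Center,8.63,275.19,13
NYU Langone Medical Center,8.48,217.50,18
City of Hope,8.07,116.71,26
Cedars-Sinai Medical Center,7.91,129.56,24
Seidman Cancer Center at UH Case Medical,7.79,82.88,28
USC Norris Cancer Hospital,7.74,19.29,34
Oregon Health and Science University,7.28,170.96,17
Yale-New Haven Hospital,6.08,114.38,17
IU Health Academic Health Center,5.95,87.41,19
Fox Chase Cancer Center,5.82,173.10,10
Cleveland Clinic,5.79,151.51,12
Thomas Jefferson University Hospital,5.06,218.84,2
University of Colorado Hospital,5.06,25.12,21
Wake Forest Baptist Medical Center,4.71,151.02,7
Hospital of the University of Pennsylvania,4.70,18.36,20
University of Maryland Medical Center,4.13,124.01,7
University of Iowa Hospitals and Clinics,4.13,72.81,12
Beth Israel Deaconess Medical Center,4.02,128.88,6
Mayo Clinic Scottsdale,3.88,0,18
University of Kansas Hospital,3.70,32.22,14
UC San Diego Medical Center,3.06,22.26,12
Hackensack University Medical Center,2.08,37.28,6
Nebraska Medical Center,1.94,9.96,8
Hahnemann University Hospital,0.43,0.00,2
Mayo Clinic Jacksonville,0.18,8.58,0
Houston Methodist Hospital,0,0,0
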