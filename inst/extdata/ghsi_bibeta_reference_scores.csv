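code,alternative,t_ci_2021,b_ri_2021,score_2021,rank_2021,t_ci_2019,b_ri_2019,score_2019,rank_2019
USA,United States of America,3.46,4.05,85.46,1,3.5,4.09,85.44,1
AUS,Australia,3.35,4.05,82.53,2,3.34,4.09,81.69,2
GBR,United Kingdom,3.34,4.05,82.29,3,3.14,4.09,76.63,9
CAN,Canada,3.30,4.05,81.48,4,3.16,4.09,77.22,8
FIN,Finland,3.23,4.05,79.69,5,3.19,4.09,78.02,3
KOR,South Korea,3.19,4.05,78.72,6,3.13,4.09,76.59,10
DEU,Germany,3.18,4.05,78.54,7,3.12,4.09,76.2,12
SVN,Slovenia,3.15,4.05,77.66,8,3.13,4.09,76.45,11
NZL,New Zealand,3.11,4.05,76.75,9,3,4.09,73.38,14
DNK,Denmark,3.09,4.05,76.28,10,3.16,4.09,77.27,7
THA,Thailand,3.09,4.05,76.19,11,3.18,4.09,77.62,4
SWE,Sweden,3.09,4.05,76.17,12,3.17,4.09,77.39,6
BGR,Bulgaria,3.03,4.05,74.65,13,2.97,4.09,72.47,17
FRA,France,3.02,4.05,74.53,14,2.99,4.09,73.06,15
NLD,Netherlands,3.01,4.05,74.18,15,3.17,4.09,77.41,5
CHE,Switzerland,3.00,4.05,73.99,16,3.05,4.09,74.65,13
GNB,Guinea-Bissau,3.00,4.05,73.94,17,2.93,4.09,71.48,20
ARM,Armenia,3.00,4.05,73.9,18,2.97,4.09,72.57,16
ESP,Spain,2.98,4.05,73.4,19,2.92,4.09,71.37,21
IRL,Ireland,2.96,4.05,73.09,20,2.9,4.09,70.75,24
AUT,Austria,2.95,4.05,72.88,21,2.92,4.09,71.28,22
YEM,Yemen,2.95,4.05,72.85,22,2.75,4.09,67.25,40
ERI,Eritrea,2.95,4.05,72.74,23,2.8,4.09,68.35,33
SOM,Somalia,2.94,4.05,72.58,24,2.93,4.09,71.53,19
MEX,Mexico,2.94,4.05,72.57,25,2.85,4.09,69.68,27
NOR,Norway,2.93,4.05,72.28,26,2.96,4.09,72.37,18
SYR,Syria,2.93,4.05,72.18,27,2.78,4.09,68.04,35
LVA,Latvia,2.92,4.05,71.98,28,2.9,4.09,70.84,23
PRK,North Korea,2.87,4.05,70.88,29,2.75,4.09,67.19,41
LTU,Lithuania,2.87,4.05,70.79,30,2.65,4.09,64.67,67
BDI,Burundi,2.87,4.05,70.69,31,2.73,4.09,66.8,44
JPN,Japan,2.86,4.05,70.55,32,2.86,4.09,70.01,25
SGP,Singapore,2.85,4.05,70.41,33,2.86,4.09,69.97,26
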