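drug,target,kon_M_per_s,koff_per_s,t_half_min,kd_M
Aliskiren,Renin,4.00e5,1.1e-4,105,3.00e-10
Aclidinium,Muscarinic M3 receptor,1.10e6,2.0e-5,578,1.80e-11
Ipratropium,Muscarinic M3 receptor,4.10e6,1.1e-3,11,2.60e-10
Tiotropium,Muscarinic M3 receptor,7.60e5,7.2e-6,1604,9.50e-12
Candesartan,Human angiotensin II type 1 receptor,2.60e4,1.9e-4,61,7.40e-09
Telmisartan,Human angiotensin II type 1 receptor,9.10e4,1.5e-4,77,1.70e-09
Granisetron,5-HT3,7.50e5,7.5e-4,15,1.00e-09
Lapatinib,ERBB2/EGFR,1.30e4,3.9e-5,296,3.00e-09
Desloratadine,Histamine H1 receptor,3.20e4,3.2e-5,361,1.00e-09
Amlodipine,L-type calcium channel,1.50e5,3.0e-4,39,2.00e-09
Verapamil,L-type calcium channel,9.20e7,2.8e0,0.004,3.00e-08
Phenytoin,Na+ channel,2.50e4,5.0e-1,0.02,2.00e-05
Amprenavir,HIV-1 protease,4.40e6,4.9e-3,2,1.10e-09
Atazanavir,HIV-1 protease,1.70e6,6.9e-4,17,4.00e-10
Indinavir,HIV-1 protease,1.50e6,1.6e-3,7,1.10e-09
Lopinavir,HIV-1 protease,6.60e6,6.5e-4,18,1.00e-10
Ritonavir,HIV-1 protease,3.90e6,2.2e-3,5,6.10e-10
Saqunavir,HIV-1 protease,8.20e5,2.3e-4,50,3.20e-10
Nelfinavir,HIV-1 protease,6.60e5,6.7e-4,17,1.60e-09
Boceprevir,Hepatitis C virus nonstructural protease (NS3),2.40e3,4.9e-5,236,2.00e-08
Ciluprevir,Hepatitis C virus nonstructural protease (NS3),9.10e5,7.3e-4,16,6.20e-09
Telaprevir,Hepatitis C virus nonstructural protease (NS3),2.20e3,9.6e-5,120,4.30e-08
Deoxy-conformycin,Adenosine deaminase,2.40e6,4.8e-6,2406,2.00e-12
Efavirenz,HIV-1 reverse transcriptase,1.40e1,6.8e-5,170,5.00e-06
Elvitegravir,HIV integrase,2.10e6,8.3e-3,1,4.00e-09
Raltegravir,HIV integrase,2.50e5,2.5e-3,5,1.00e-08
Methotrexate,Chicken dihydrofolate reductase,3.70e7,3.3e-4,35,9.00e-12
Trimethoprim,Escherichia coli dihydrofolate reductase,7.20e7,1.4e-3,8,2.00e-11
Oseltamivir,Viral neuraminidase,7.90e5,2.5e-4,46,3.10e-10
Saxagliptin,Human dipeptidyl-peptidase IV,1.60e5,5.4e-5,214,3.50e-10
Vildagliptin,Human dipeptidyl-peptidase IV,8.70e4,9.8e-4,12,1.10e-08
Triclosan,Enoyl-ACP reductase (Francisella tularensis),8.20e6,4.2e-4,28,5.10e-11
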