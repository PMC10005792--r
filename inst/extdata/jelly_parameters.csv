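brand,jellies,temperature_k,c_s_dd,c_s_dd_unc,tau_s,tau_s_unc,c_i_dd,c_i_dd_unc,tau_i,tau_i_unc,c_f_dd,c_f_dd_unc,tau_f,tau_f_unc,a,a_unc
Haribo,bear|phantasia,298,1.46e8,6.1e7,2.43e-6,5.2e-7,1.00e9,1.2e7,4.83e-7,3.9e-8,1.25e9,3.2e8,5.21e-8,2.7e-9,27.0,3.2
Haribo,bear|phantasia,323,1.46e8,6.1e7,2.43e-6,,8.02e8,4.3e7,3.49e-7,2.6e-8,1.25e9,3.2e8,5.21e-8,2.7e-9,27.0,
Haribo,balla apple,298,1.46e8,6.1e7,1.64e-6,6.9e-8,5.20e8,3.3e7,3.97e-7,2.9e-8,1.25e9,3.2e8,5.21e-8,2.7e-9,40.6,5.3
Haribo,balla apple,323,1.46e8,6.1e7,1.50e-6,5.7e-8,4.12e8,2.9e7,3.00e-7,2.8e-8,1.25e9,3.2e8,5.21e-8,2.7e-9,40.6,
Haribo,balla raspberry,298,1.46e8,6.1e7,1.76e-6,1.3e-7,7.86e8,3.9e7,4.34e-7,3.0e-8,1.25e9,3.2e8,5.21e-8,2.7e-9,37.8,3.3
Haribo,balla raspberry,323,1.46e8,6.1e7,1.37e-6,3.6e-8,1.78e8,2.1e7,2.74e-7,4.2e-8,1.02e9,3.4e8,5.21e-8,2.7e-9,37.8,
Haribo,tropifruity|color-rado,298,1.46e8,6.1e7,1.92e-6,5.0e-8,7.08e8,1.6e7,4.17e-7,1.3e-8,1.25e9,3.2e8,5.21e-8,2.7e-9,33.1,3.7
Haribo,tropifruity|color-rado,323,1.46e8,6.1e7,1.20e-6,5.8e-8,3.61e8,2.2e7,3.66e-7,3.3e-8,1.25e9,3.2e8,5.21e-8,2.7e-9,33.1,
Vidal,coke|fish|pizza,323,1.46e8,,1.53e-6,2.8e-8,6.98e8,6.9e7,2.53e-7,1.6e-8,1.25e9,,3.55e-8,6.3e-9,25.6,1.2
Vidal,cherry,323,1.16e7,3.1e6,2.55e-6,5.3e-7,1.38e8,1.7e7,3.45e-7,2.4e-8,9.11e8,3.1e7,5.61e-8,2.4e-9,38.4,2.2
Vidal,roll,323,1.46e8,,1.26e-6,3.0e-8,4.90e8,2.0e8,9.32e-8,2.6e-8,1.25e9,,9.68e-9,6.1e-9,15.1,0.8
Vidal,watermelon,323,2.94e7,8.8e7,2.44e-6,4.7e-7,1.64e8,2.5e7,4.27e-7,8.8e-8,8.79e8,6.6e7,4.39e-8,6.7e-9,35.0,3.3
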