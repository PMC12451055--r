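# Published group summary statistics (n, mean, SD; sex as M/F counts) for
# the PD-with-anxiety (pd_a), PD-without-anxiety (pd_na) and healthy-control
# (hc) groups. "alps" is the full DTI cohort; "coupling" is the subset with
# foramen-magnum fMRI coverage used for the combined gBOLD-CSF analysis.
# ALPS indices are dimensionless ratios; coupling is the correlation
# magnitude at -3 TR; ledd in mg; duration in years.
alps:
  groups: {pd_a: 21, pd_na: 47, hc: 38}
  sex_mf:
    pd_a: [10, 11]
    pd_na: [30, 17]
    hc: [19, 19]
  variables:
    age:       {pd_a: [67.00, 7.11],   pd_na: [63.00, 8.84],   hc: [62.61, 7.99]}
    education: {pd_a: [10.40, 2.19],   pd_na: [9.63, 3.27],    hc: [9.55, 3.96]}
    ledd:      {pd_a: [409.52, 230.35], pd_na: [409.84, 224.58]}
    duration:  {pd_a: [5.60, 3.65],    pd_na: [3.36, 2.38]}
    hy:        {pd_a: [2.29, 0.77],    pd_na: [1.93, 0.69]}
    updrs3:    {pd_a: [25.24, 11.66],  pd_na: [21.09, 10.66]}
    hama:      {pd_a: [19.52, 4.85],   pd_na: [5.43, 3.25],    hc: [2.61, 1.76]}
    hamd:      {pd_a: [12.43, 5.84],   pd_na: [4.06, 2.83],    hc: [3.05, 1.97]}
    mmse:      {pd_a: [28.57, 1.69],   pd_na: [28.47, 1.44],   hc: [28.97, 1.00]}
    alps_l:    {pd_a: [1.282, 0.126],  pd_na: [1.324, 0.102],  hc: [1.341, 0.128]}
    alps_r:    {pd_a: [1.240, 0.131],  pd_na: [1.317, 0.110],  hc: [1.334, 0.114]}
    alps_mean: {pd_a: [1.261, 0.124],  pd_na: [1.321, 0.101],  hc: [1.338, 0.110]}
coupling:
  groups: {pd_a: 16, pd_na: 36, hc: 34}
  sex_mf:
    pd_a: [8, 8]
    pd_na: [22, 14]
    hc: [17, 17]
  variables:
    age:       {pd_a: [66.63, 7.63],   pd_na: [62.64, 9.19],   hc: [61.35, 7.03]}
    education: {pd_a: [10.66, 2.17],   pd_na: [9.35, 3.40],    hc: [9.50, 3.88]}
    ledd:      {pd_a: [440.63, 220.58], pd_na: [380.90, 172.29]}
    duration:  {pd_a: [5.84, 3.75],    pd_na: [3.10, 2.17]}
    hy:        {pd_a: [2.34, 0.79],    pd_na: [1.79, 0.60]}
    updrs3:    {pd_a: [25.50, 12.19],  pd_na: [20.36, 11.45]}
    hama:      {pd_a: [18.88, 5.06],   pd_na: [5.25, 3.29],    hc: [2.68, 1.79]}
    hamd:      {pd_a: [11.25, 4.57],   pd_na: [4.03, 2.72],    hc: [3.26, 1.96]}
    mmse:      {pd_a: [28.75, 1.77],   pd_na: [28.47, 1.38],   hc: [28.91, 1.03]}
    coupling:  {pd_a: [0.230, 0.143],  pd_na: [0.363, 0.194],  hc: [0.337, 0.177]}
    alps_l:    {pd_a: [1.282, 0.119],  pd_na: [1.324, 0.105],  hc: [1.335, 0.130]}
    alps_r:    {pd_a: [1.231, 0.113],  pd_na: [1.317, 0.114],  hc: [1.341, 0.119]}
    alps_mean: {pd_a: [1.256, 0.110],  pd_na: [1.320, 0.105],  hc: [1.338, 0.115]}
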