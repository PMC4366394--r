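measure,sex,age_group,n,mean,sd
rostrum,male,infant,19,10.2,6.2
rostrum,female,infant,10,9.7,4.5
rostrum,male,child,18,13.8,6.0
rostrum,female,child,21,14.0,4.3
rostrum,male,adolescent,17,15.3,7.1
rostrum,female,adolescent,15,14.4,4.3
rostrum,male,adult,7,24.7,12.03
rostrum,female,adult,7,18.1,6.1
genu,male,infant,19,55.1,28.8
genu,female,infant,10,63.7,25.7
genu,male,child,18,108.6,15.4
genu,female,child,21,111.6,15.1
genu,male,adolescent,17,127.9,26.4
genu,female,adolescent,15,126.5,29.2
genu,male,adult,7,151.9,24.5
genu,female,adult,7,121.3,18.3
rostral_body,male,infant,19,52.5,18.5
rostral_body,female,infant,10,49.4,17.1
rostral_body,male,child,18,70.0,14.0
rostral_body,female,child,21,70.0,12.8
rostral_body,male,adolescent,17,86.4,17.8
rostral_body,female,adolescent,15,75.7,11.8
rostral_body,male,adult,7,83.6,10.2
rostral_body,female,adult,7,88.1,10.4
anterior_midbody,male,infant,19,31.3,13.2
anterior_midbody,female,infant,10,30.5,10.4
anterior_midbody,male,child,18,52.5,8.3
anterior_midbody,female,child,21,51.0,6.9
anterior_midbody,male,adolescent,17,65.7,10.2
anterior_midbody,female,adolescent,15,61.7,10.6
anterior_midbody,male,adult,7,69.6,10.6
anterior_midbody,female,adult,7,63.3,8.3
posterior_midbody,male,infant,19,28.4,9.5
posterior_midbody,female,infant,10,27.6,10.6
posterior_midbody,male,child,18,46.0,8.8
posterior_midbody,female,child,21,48.5,6.8
posterior_midbody,male,adolescent,17,57.7,7.4
posterior_midbody,female,adolescent,15,57.3,14.2
posterior_midbody,male,adult,7,62.3,15.9
posterior_midbody,female,adult,7,60.6,6.8
isthmus,male,infant,19,19.9,7.4
isthmus,female,infant,10,20.9,6.8
isthmus,male,child,18,35.6,9.3
isthmus,female,child,21,36.4,9.3
isthmus,male,adolescent,17,44.1,8.5
isthmus,female,adolescent,15,43.4,9.2
isthmus,male,adult,7,52.4,12.1
isthmus,female,adult,7,45.7,7.1
splenium,male,infant,19,84.8,35.9
splenium,female,infant,10,82.3,22.7
splenium,male,child,18,135.4,23.4
splenium,female,child,21,141.6,21.5
splenium,male,adolescent,17,169.5,20.3
splenium,female,adolescent,15,162.5,37.8
splenium,male,adult,7,175.4,12.5
splenium,female,adult,7,177.9,21.6
total_cc,male,infant,19,282.2,112.5
total_cc,female,infant,10,284.1,87.0
total_cc,male,child,18,461.9,64.8
total_cc,female,child,21,473.0,53.6
total_cc,male,adolescent,17,566.6,67.3
total_cc,female,adolescent,15,541.5,89.0
total_cc,male,adult,7,541.5,89.0
total_cc,female,adult,7,575.0,57.1
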