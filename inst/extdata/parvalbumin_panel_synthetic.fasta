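>Clu h 1.0101
MSSCAAIQQWDGFRKMIGAMMCCWFWRCANYSFSCFEQTCLQPMMMGWLQEPECFVCFKPAYGTANATLGMVMPRGNSCTGNNCYVACKLWKEKPGEMIMEFNMHRMKE
>Clu h 1.0201
MSSCAAIQQMDGFRKMIGAMMCCWFWRCANYSPSCFPQTCMQPPMHGWLQEPECFVCFGVASGTANATLGMVMPYGNSCHGNNCCVACKLWKEVPGEMIMEFNMHRMKE
>Clu h 1.0301
MSRCAAIQQMDGFRKMIGAMMCCFAWRCANYSMSCFPQTCLQPMMHGWLQNPECFVCFGVASPTANATLGMVMPYGNSCSGNNCCVACKLWKEKPGEMIMEFNMIVMKE
>Cyp c 1.0101
MSSCAAFQQMDGFRKMIGAMQCCWFWRCVNYSFGCFPQTCLQPMMHGWLTEPECFVCFGVASGTANATLGMVMPYGNSCSGNNCCVACKLWQEKPGEDSMEFNMHRMIE
>Cyp c 1.0201
MSSCAAIQQMDGFRKMTGAMMICWFERCANYSFSCFPQTCLQPMMHGKLQEPECFVCFGVAPGTAQATLDMVMPYSNFCSGNNCCVAAKLWKEKPGEMIMEFNMHRMKE
>Gad c 1.0101
ASSCAAIQQMDCFCKMIGAMMCCSKWRCANYSFSCFPQTCVQPMMHGGLQEPECFVCFGQASGTANARLGMVMPYGNSCSGNNCCVACALWKEKPFEMICPFNMHRMKE
>Gad m 1.0101
MSSCAAIQQMCGWRKMDGAMMCCWDWRCANYSFECFPSTCLQPMMHGWLQEPECFVCFGVASGTANATLGMVMPYWNSCSGNNKCVACKLWKEKPGEMIMEFNMHRMKE
>Gad m 1.0102
MSSCTAIQQMDGFRKMIGAMMCCWFWRCANYSFSCFAQTCLQPMMEGWLQEAECFVCFHVASGTASATLFMKMPYGNMCDGNNCCVACKLWCEKPWEMQMEFNMHLMKE
>Gad m 1.0201
MSSCAAIQQMDGFRKMQGAMECCWFWRCLNYSLAAKSPADIQPMMHGWLQEWRCFVCFGVASGTANATLGMVMPYGNYESGNYCWVACKLWKEKPGEMIMEFNMFRTKE
>Gad m 1.0202
MSSCAAIQQMDGFRKMIGAMMCCWFWRCANYSKSCFPHPCLQPMHHGWLQEPECFVCFGVASGTANATLGMVMPYGNSCSGNNCCVACKLWKEKPGEMIMHFNMHRMDE
>Lat c 1.0101
MSSCAAIQQMDGFFKMIGAMMCCWFWRCANYSFSCFPQTCLQPMMHGWLQESECFVCFGVASGTANATLGTVKPYGSSCSGNNCCECCKEWMEKPGFMIMEFNMHRMKE
>Lat c 1.0201
MSSCANIQQMDGFRKMWGAMVCCWFWRCANYSFSCFPQTCLQPMMHGWLQEPECFVCPIVASGTANATLGMVMDYSNSCSGNNCCVAAKLWKEKPGEMIMVFNMMRMSE
>Lep w 1.0101
MSSCAWIQQIDGFRKMIGAAMCCWFGRCANQSFSCFPQTCLQPKMYGWLQEPECFVCIGVASTTANATLGMVMPQGNSCSGNNCCVHCDLWKEKPGEMYMEFNMIRMKE
>Onc m 1.0101
ASSCAAEQQMDGFRKMIGACMCCWFWRCANYSFSCFPQTCLQPMMHGWLQWPECFVTFGVASNTAAATLGMVMPYGNSAS
>Onc m 1.0201
ASYCAAIQQMDGFRKMSGAMMCCWFWRCANYSQSCFFQTCLQPMMHGWLQRPECFVCFLVASGTANATLEMVMPQGNSCS
>Sal s 1.0101
MSSCAAIQKMDGFRKMIGRMMCCWFWRCANYSFSEFPQTCLQPMRHGWLQEPECFVCFGVASGTANAILGMVMPYGNSCSGNVCCVACLLCKEKPGYMIMEFNMHRMKE
>Sar sa 1.0101
MWSCAAIQQMDGFRKMIGAMMCCWFWRMANYSFSCFPQGCLQPMMHGILQEPECFVYFGVASGTANATLGMVKPYGNSCSGNNCCVACKLWKEKPGEMIMEFNNCRMKE
>Seb m 1.0101
MSSCAAIQQMDSFRKMIGAMMCCWFFRCANYSFSEFPQTCLQPMMHGWLQEPECFVCQGVASGYANATLGMVYPYGNSCSGNNCCVACKLWKEKPGEMIMEFNMHRMKR
>Seb m 1.0201
MSSCAAIQQMDGFRKMIGAMMCCWFWRCANVSFSCFPQTCLQPMMHGWLQEPECFVCWGVWSGTANATLGMVMPYGNSCNGGNCGVACKLWKWKPGEMIMEFKMHVMKE
>Thu a 1.0101
MSSCAAIQQMDGFRKMIGAMMCCWFWRCANYSLAAKTPEDIQPMSHLWLQEPICFVCFFIEEDELKLFLQNFSAYGNSCSSNFCCVTCKLWKFIPGEMIMEFNMHRMKE
>Xip g 1.0101
MSSCAAIQQMDGGRKDIGAMMCCWFWRCANYSFSCFPQTCLQFYLHGWLQVPECFVCFGVASFTANATLGMVMPYGNMCSCNNCCVACKLWSEKPSEMIMEFNMHRMKE
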