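>STS_syn_01
WVGRTIDINCITVQHIPIKIEGTGSKDIVHTAKGYRMLYDLVYQHAYNRWELDTNYCHEWTWCMKDSYFQCVYFRNNEIS
YPMSMGLRYTRWEHYAMAHFIPAYRLMALNYAQFPACPTLAGVMELIMAMTTEVAEREAAPVIHKNKAVCLCCLDNTEVN
PFKEKQHRKDVPYGRKSVDIRHHDWSVVDAWSLEMRGVLLNVYNCLRARGAKKPCDWEFSPFKHWFYCYCYFASLSHHDI
LANVLAITRVIYGQVPSPNFILTFYMLDRACYVAGQWSDISTKFRPHPCENDRTFMKLARPDERNYWLKGQCWMFCMIKF
MEGICWYNHGVCKEKITMPGVTMLNTGRRFNCSTGLAQKSWLSDYQAEADHHHKHYMFKESQVQYYQLWMKFGSR
>STS_syn_02
WRARCINIQCITVQHIPIKIEGTMSKDIVHTAKGYRMCYDLVYQHAYNRWELDTKYCHEWTWQMKDSYFQCVYFRNNEIS
YPDSMGPAYIELEHYAMAHKIDEYRLMALNTAQFAACPTIVGVMELIMAMTVEVAEREAAPVIHKNKARCLCCLGNTEVN
PIKEKQHRKDNPYGRKLVDIRHHDWSVVDAWSKEMRGALLYWYTWLRARGPKKPCDWERSPFKHWFYCFCYFANLSEDDI
LALVLAITRRIYGQHPNPNFILEFYMLDTACYYAGQWSDISTKFRMHGCENDRTFMKGACADKTNYMLMGQCWSFEEWWF
MCGIQWYNFGVCCEKICMQGATMLNTQRRFNCPTGLVQKSWLSDYQAIRDHGHKVNMFKESQVQYYQLKMKFGIR
>STS_syn_03
WVARCIDIQCITVFHIPIFIEGWMSKNIVHTATGYRMLYDLVYQHAYNRWELDTKYCHEWTQQMKDSYFQCVYFRNNELS
YPMSMGPRYNEFEHYAFAHPIPAYRLMALNTAQFPACPTIVKVMELITSLTSEYAEREAAPVIHKNKAFCLCCLDNPEVN
PMKEKQHRKDNPYGWKSVFLRHYDWSDVDAWSKEMRGALLYYYNWLRARGPKGMCDWERSPFKHWFYCYCYFPELSHDDW
LALVLPITRVIYDQVPSPNFWLEFYMLDTACYVAGQWSDISTRFRPHPCENDRTFMNLACPDERPYHLMGQCWMFCEQWF
HETICWYNFGVCCEKICMQGVTMVNTGRRFNCSTGLEQHAWLSDYQAIADHHHKVKMFKESQVNYYQLKMKFGIR
>STS_syn_04
YVARCIDNQCITVQHEPIKIEGTMSKDIVHWAKGYSMLYDLVYQHAYNRIELDDKYCHEWTWQMKDSYFQCVYFRNNEIS
YPMSMGPRRTEWEHYAMAHKIGAYRLMALNTAPFPACPTIVGVMELIMAMTTEVAEKEAAPVIHKNKAVCLCCLDTTEVN
KMKEKQHRKDNPYGRKSVDIRHHDWSVVDAFSKKMRGALLYVGNWLRARGPKKPCDWERSPFKHWFYCYCYFAELSHDDI
LASVLNITRVIYGQVPSPNFILEFYMLDTACYVACQWSMISTKFRPHPCENDRTFPKLACPDERNRHLQGQNWMFYEIWR
MEGICWYNFGNCCEKICMQRVTMLNTGRRFNCSTGLVQKSWLSDYQAIADHHHKVKMFKESQVQYYQLKKKFGNR
>STS_syn_05
WVGRCIDIQCITVQHTPIKITGTMSKAIVHTAKVYRMLYDLVYQHAYNRNELRTKYCHEGTCQMKDSYFQCVYFRNNEIS
SPMSMGPRYTEWDHLRMAHPIPAYRLMALNTLQFPACPECVGVMRLIMAMTTEVAEREAAPVIHKYKAVCLCCLDNTEVN
PMKEKQHRKDNPYGRKSVDIWHHDWCVVDAWSKEMEGALLYVYNWLRARGPKKPCDWERSYFKHWFYCYCYIAELSHDGS
LALVLAITRVIYGKVPSPDLILEFYMLDTACYVAGQWSDISTKFRNHPCENDRTFMKLACPRVRNYHDMGQCWMFCEIWF
MEGICWYNFGVCCETICMQGVTMLHTGKRTNCSTGLVQNSVSSDYQHIADHHHEVKMFKESQVIYYQLKMKFGIS
>STS_syn_06
WVARCIDIQMITHQHNPINIGGTMSKDIVHTAKGYWMLYDLVYQHAYNHWPLDTKYCHESTWQMKDSYFQCVYFVYNEIS
TPMWMGPRYTEWEHYAMAHKAPAYRLMALNTAQFPACPTIVGVMELIMIMTTEVAERELAPVIDKNAAVCLCCLDNTEVN
PMKEKQHRKDNPYGRKSVDIRHHDWSVVDAWSKEMRGALPYVYNWLRARGPKKPCTWERIPFKHWFYCYCYTAELSHDDI
LAAVLAATRVIYFQYPSPNFFLEFYMLDTACYVTGQWSIIETKFRPMPCENDRTWMKLACPDERNYHLMGQCWMFCEIWF
MEKICWYNFGVLCEKGCMQGVTMLNTGLRFNCSTGLVQNSWLSDYQAIADHHEKVKMFGESQVQYYQLKMKFGIE
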