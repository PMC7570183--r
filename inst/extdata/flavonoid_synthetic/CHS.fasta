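>CHS_syn_01
WVGRTIDINCITVQHIPIKIEGTGSKDIVHTAKGYRMLYDLVYQHAYNRWELDTNYCHEWTWCMKDSYFQCVYFRNNEIS
YPMSMGLRYTRWEHYAMAHFIPAYRLMALNYAQFPACPTLAGVMELIMAMTTEVAEREAAPVIHKNKAVCLCCLDNTEVN
PFKEKQQRKDVPYGRKSVDIRHHDWSVVDAWSLEMRGVLLNVYNCLRARGAKKPCDWEFSPFKHWFYCYCYFASLSHHDI
LANVLAITRVIYGQVPSPNFILTFYMLDRACYVAGQWSDISTKFRPHPCENDRTFMKLARPDERNYWLKGQCWMFCMIKF
MEGICWYNHGVCKEKITMPGVTMLNTGRRFNCSTGLAQKSWLSDYQAEADHHHKHYMFKESQVQYYQLWMKFGSR
>CHS_syn_02
WRARCINIQCITVQHIPIKIEGTMSKDIVHTAKGYRMCYDLVYQHAYNRWELDTKYCHEWTWQMKDSYFQCVYFRNNEIS
YPDSMGPAYIELEHYAMAHKIDEYRLMALNTAQFAACPTIVGVMELIMAMTVEVAEREAAPVIHKNKARCLCCLGNTEVN
PIKEKQQRKDNPYGRKLVDIRHHDWSVVDAWSKEMRGALLYWYTWLRARGPKKPCDWERSPFKHWFYCFCYFANLSEDDI
LALVLAITRRIYGQHPNPNFILEFYMLDTACYYAGQWSDISTKFRMHGCENDRTFMKGACADKTNYMLMGQCWSFEEWWF
MCGIQWYNFGVCCEKICMQGATMLNTQRRFNCPTGLVQKSWLSDYQAIRDHGHKVNMFKESQVQYYQLKMKFGIR
>CHS_syn_03
WVARCIDIQCITVFHIPIFIEGWMSKNIVHTATGYRMLYDLVYQHAYNRWELDTKYCHEWTQQMKDSYFQCVYFRNNELS
YPMSMGPRYNEFEHYAFAHPIPAYRLMALNTAQFPACPTIVKVMELITSLTSEYAEREAAPVIHKNKAFCLCCLDNPEVN
PMKEKQQRKDNPYGWKSVFLRHYDWSDVDAWSKEMRGALLYYYNWLRARGPKGMCDWERSPFKHWFYCYCYFPELSHDDW
LALVLPITRVIYDQVPSPNFWLEFYMLDTACYVAGQWSDISTRFRPHPCENDRTFMNLACPDERPYHLMGQCWMFCEQWF
HETICWYNFGVCCEKICMQGVTMVNTGRRFNCSTGLEQHAWLSDYQAIADHHHKVKMFKESQVNYYQLKMKFGIR
>CHS_syn_04
YVARCIDNQCITVQHEPIKIEGTMSKDIVHWAKGYSMLYDLVYQHAYNRIELDDKYCHEWTWQMKDSYFQCVYFRNNEIS
YPMSMGPRRTEWEHYAMAHKIGAYRLMALNTAPFPACPTIVGVMELIMAMTTEVAEKEAAPVIHKNKAVCLCCLDTTEVN
KMKEKQQRKDNPYGRKSVDIRHHDWSVVDAFSKKMRGALLYVGNWLRARGPKKPCDWERSPFKHWFYCYCYFAELSHDDI
LASVLNITRVIYGQVPSPNFILEFYMLDTACYVACQWSMISTKFRPHPCENDRTFPKLACPDERNRHLQGQNWMFYEIWR
MEGICWYNFGNCCEKICMQRVTMLNTGRRFNCSTGLVQKSWLSDYQAIADHHHKVKMFKESQVQYYQLKKKFGNR
>CHS_syn_05
WVGRCIDIQCITVQHTPIKITGTMSKAIVHTAKVYRMLYDLVYQHAYNRNELRTKYCHEGTCQMKDSYFQCVYFRNNEIS
SPMSMGPRYTEWDHLRMAHPIPAYRLMALNTLQFPACPECVGVMRLIMAMTTEVAEREAAPVIHKYKAVCLCCLDNTEVN
PMKEKQQRKDNPYGRKSVDIWHHDWCVVDAWSKEMEGALLYVYNWLRARGPKKPCDWERSYFKHWFYCYCYIAELSHDGS
LALVLAITRVIYGKVPSPDLILEFYMLDTACYVAGQWSDISTKFRNHPCENDRTFMKLACPRVRNYHDMGQCWMFCEIWF
MEGICWYNFGVCCETICMQGVTMLHTGKRTNCSTGLVQNSVSSDYQHIADHHHEVKMFKESQVIYYQLKMKFGIS
>CHS_syn_06
WVARCIDIQMITHQHNPINIGGTMSKDIVHTAKGYWMLYDLVYQHAYNHWPLDTKYCHESTWQMKDSYFQCVYFVYNEIS
TPMWMGPRYTEWEHYAMAHKAPAYRLMALNTAQFPACPTIVGVMELIMIMTTEVAERELAPVIDKNAAVCLCCLDNTEVN
PMKEKQQRKDNPYGRKSVDIRHHDWSVVDAWSKEMRGALPYVYNWLRARGPKKPCTWERIPFKHWFYCYCYTAELSHDDI
LAAVLAATRVIYFQYPSPNFFLEFYMLDTACYVTGQWSIIETKFRPMPCENDRTWMKLACPDERNYHLMGQCWMFCEIWF
MEKICWYNFGVLCEKGCMQGVTMLNTGLRFNCSTGLVQNSWLSDYQAIADHHEKVKMFGESQVQYYQLKMKFGIE
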