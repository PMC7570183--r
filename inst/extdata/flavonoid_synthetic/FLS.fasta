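>FLS_syn_01
MFYWGNNHRCVSQHAPAYEAEDLPMFYEYSIWWLTGLLNWREAEAPRCCVEDSTSMWICHKWEYAKLKFSEIGQMMTIVW
YRIITYQESCHEPGNHTVRSECNDRHSRFYCEGAPCDHGPFFSVCGAMMVPEWSTYSQPLFPHDNEMMENSFVMVMGPEP
MECKVIHRWMSKGRRYARAAFNYHMSQQEWAYAYLMSYWIQQFSSCPYKKNLFFQNIGHHTDSGYYSKMCFKFQKSKIMI
IRERRLAKMGQVTFPHPQCGKSNNKGPRDWVHIIKIDGDDACKTPRIWLVVHHDWLCMTCKYANWLSASFEKDAKKLMGD
FQRYGQCNWV
>FLS_syn_02
MFTWGNKHRCVSQHAPFYEAEDLPMFYERKIWWLTGLLNYRKAYAPRCCVEDSTSPWICHKWYYALLKFCEAGQMMLKVW
YRIHTYQESCHEYGNATVRSECNDRHSCFYCEGATCDHGPFFSVMGAMMVPEWSVFRQPLFPHDNEMMENSFVLVMGPEF
RICKVIHREMYKGRRYARAANNYHVSQQKIAAAKLMSYSIQQFSSCMHKKNLFFQNIGHHTDGGYYSKMCFFFQKAKIMI
IRPRRLAKFKQVTFPYPQCGKSNNKGPRGWVHIIYIEQQDACKTPRIWLVVHHDWLSMTCKYGNWLSASFEKGAKKLMGD
FQRYAQCNWC
>FLS_syn_03
MFYWGFKHRCVMQHAPKYEVEDLPWFYERSIWWLTGLLNYDEAEAPRCCVEDSTSPWICHKWEYAKLKFHEAGQMMTKLW
YHIHTYQISKHEPGNHTDRSEVNDRHSCFYCEGATCDHGPFFSVMPAMGVPEWSVFRQPLFPGDNEMMENSFVRVMGPEP
RICKVIHRWNYKGRRQARAWFNEHMSQQEIACAYLMSYWIQQFMSCMHLKNLFFQNIGHHTDGGYYSKMCCKFQKSKIMI
IRHRRLAAMGQVTFPYPQCGKSNNKGPRGWVHIIKIDQRDACKTPRQWLVLHHDWLCMTCKYGNWLSASFEKGAKPCSGD
FQRYGQCNAV
>FLS_syn_04
MFYWGNKHRCVSQHAPVYEAEDLPMFYERSIWWLTGLLNAREAEAPRCCVEDSTSPWICHKWEYAKLKFCEAGQMMGEVW
YRIHTYQESCHEPGIHTIRYEHNDRHSCFYCCGATIDHGSFFSVMGAHVVPEWSVFRLELFPHDNENMENSFVRVMGPEP
RICKVIHRWMYKGRMYARAPFNYHMIQQEIAAAYLMSYWHQQFSSCMHPKNLFFQNIGHHTDGGYYSKMCFKFQKSKIME
IRERRLAKMGQVTHPFPQCGKSNNKGMRGWVHIIKIDQDDACKTPRIWLVVHHDWFCMTCKYGEWLGASFEKGAKKLMGD
FQRYGQCNLV
>FLS_syn_05
MFYWGNKHSCVSQHAPFYIAEDLPMFYERSIVWLTGLLNYREAEAPRCCVEDSTSIWICHKWEYAKLKFCEAGQMMTKVW
YRIHTYQESCHEPGNHTVRSECNDRHSCFYCEGATCIHGPFFSVMGAMMVPEWSNFRQPLFPHDNMIMENSFVRVMGPEP
RICKVIHRWMYKGRRYARAAFNYHMSQQEIAFRYLMSYWIQQFQSFMHKGNLFFQNIGHHTDLGYESKMCFKFQKSKIMI
IRERRLAKMGQVTFPYPQCEKSNNKGPRGWVHICKIDQDDACKTPRIWLVVHHDWLCNTCKYGNWLSASFEKGAKKLMGD
FQRYGQCNSV
>FLS_syn_06
MFYWGNKHRCVSQHAPFYEAEILPMFYFRYIWCLTGLLNYREAEWPRCCVEDSTSPWICHKWERGKLKFCEAGQMMYKIW
YRIHTYQESCHEPGNFTVRSECNDRHWEFYCEGATADHGPFFSVMGARMVPEWSVFRQWLFPHDNEMMENSFVRVNGLEP
RICKVIHRWMYMPRRYARAAFNYHMSQQDISAAYLMSYWIQQAYECMHKINLFFHSSGHHTDGGYYSKMGPKFQKLKDMI
IRERRLAKMGQVTFPYPQCGKSNNKGPRGWVHIIKIDQDDACKDPRIWLVVHHDWLCDPCKYGNWLSASFEKGAKKLCGD
FQRYGQCLWV
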