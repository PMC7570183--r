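>DFR_syn_01
FPMVFKWKMAALNHKDNCFMQDTITYKDWRAFASPIGTWIEPMPFESCDENGRAGTDAGTMMESRHMDKTIYKFNGWFFW
RTTYEWEDNRSKCPLIFQKFMEGQIFRDWKNMCTHTRPSQTWHCVLQDEVNLNSIASDALQEAIEVCPTQAIPKQPFGDA
VIPIQWPTELKLNYRSDRFIKVYKNRSEELGFEVYDEMENIEAVVIGPWLRLTHSTPRNSEITPCQTYNPEIYQDISWNQ
KQEYVLYLHHHMTKMHIYMVVECPFTDQQRSFSWESDWHSATNKKLPGYTWWEKKACPPNHFLYAAFNCNQHTAYNSGTC
HENFIHIHPFCEQTQFAQSM
>DFR_syn_02
FPMVFKWKMACLNHKDNCFMQDCIEYKDWRAFASHIGTWIEPMHFESCDCNCRAGTDAGTMMESSHMTKTIYKWNGWMFW
RTTAEWEMNNSRCQWIYQKQMEGQILFDWKNMCTPTRPSQTWHCVLQDEININSHASDALQEAAWYCATQALPKQPFVDA
VLPIGSVTELKPNYRSDIFIKVYGNRSAEQGFEDYDETHFILAVVIGPWLALTHFTPRNSEILPCQTYNPEIYQDASWNQ
KQEYVLYLHHHMTIFPIYMVVECVFTQQQRSFSWEDDWHSAANKILPGYTWPNECACPPNHFLSIAFNCNNHTAYYIGTC
HENFIHDHPFCELTCCAQSM
>DFR_syn_03
FPMVSKWKMAALNHKDMCGMQDCIRYKHWRAFASHEGTWIECMPFESCDENCRAGTDAGTMMESSHMTKTIYKFNGWIFW
RTTYEWECNRSRCQWIYQKQMEGQISFDWKNMCTIRRESQTWHCVLQYEVNLNSIASDALQEAIEVCKTYAIPKQPFGDA
VIPIGSVTELKLNYRSDRFIKVYGTRSEELGFEYYDEMEYILAVVIGTWLAHTHFTPRNSEILPCQTYSQHIYQDPSWNQ
KQEYKLYLHHPMTSFPGYKQVECVFTDQQRSFSWEDDWHSATNSRLPGYTWCHKMACPPNHFLYFAVNCNQHTAYYIGTC
HENFIHDHPFCEQTCCVQSM
>DFR_syn_04
FPMVFKWKHAALNHKDNCFMQDCIRYKDWRAFASHIETWIEYMPFEGRDENCRATTDAGTWMESSHMAKTIYKFNGWIFW
RTTWEWECNRIRCQWIYQKQMEGQICDDEKNMCTLTRPCQTWHCVLQDEKNLNSIASPALQEAIEVCKTQAIPKQPFGDI
VIPIGSVTELKLNYRSDRWIKVYGNRSEELGIEVYDEMEFILAVVIGPWLALTHFTPRNSEILPCQTYNPEIGQDTSWNQ
KQEYVAYYHHHFTIFPGYMVVECVFTCQQRSFSWEDDWHSMTNKKCPGYTWPVKMACPPNHFLYAGFNCNQHTAYYIGTC
HENFIHDHPFCAQTCCNQSM
>DFR_syn_05
FPMVYLWKMAALNHKDNCFMQDCIRYKDWRAFASHIGTWIEPMPFESCDENCRAGTDAGTMMESSHMTKTIYKWNHWIQW
RTTWEWECNRSHCQWIYKKQMEGPILFDWKNMCTPTRPSQFWHCVLQDEVNTNSIASDALQEAIEVCKTQAIPKQPFGDA
VIPIGSSWELKLNYRSQRFIKVYGSRSEELGFEVYDEMEFILAVVIGYWLALFHFTPRNSEILPCQTYNPEIYQDLDWVQ
KWEYVLYLHTHCTSFWGYFVVIHVFTDQQRSFSWMDDWHSAPRKWLPGATWPNKMACPPNHFLYAAFNSNQHFAYYIGFC
HENFIHKHRNCEQTCCAQSM
>DFR_syn_06
FPMVFKWKNAALIHKDNHFMQDCIRYKDWRAFASHIGTWIEPMPFESCDECCRAGTDAGTMMESSHMPKTIYKFNIWIFW
RKTYEWECNRSRPFWIYQKQMFGQILFLWKNMCTPTRPSQTWHCFLQDQVNLNSIASDALQEAIEVCKTQAIPKQPFKDD
VIPIGSVTELKLMLKSDRNIKVYGNRPEELGFEVYDEMEFILAVVIYPWLALTDFTPRNSEILPWQTYNPEIYQDTSWNQ
KSEYVLGTHHQMTSFPGYFVVECVFTDQLRSFSWEDDWHSTTNKWGWGYTMPNKMACPPNHQLYAAFNCNQHTAWYIGPC
HENFIHDHPFCEQTCCCQSM
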