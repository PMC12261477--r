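>phi29_DNAP_C3 thermostable DNA polymerase mutant used as scoring template
MKHMPRKRYSCDFETTTKVEDCRVWAYGYMNIEDHSEYKIGNSLDEFMAWALKVQADLYFHNLKFDGAFI
INWLERNGFKWSADGLPNTYNTIISRMGQWYMIDICLGYKGKRKIHTVIYDSLKKLPFPVKKIAKDFKLT
VLKGDIDYHKERPVGYKITPEEYAYIKNDIQIIAEALLIQFKQGLDRMTAGSDSLKDFKDIITTKKFKKV
FPTLSLELDKKVRYAYRGGFTWLNDRFKEKEIGEGMVFDVNSLYPAQMYSRLLPYGEPIVFEGKYVWDED
YPLHIQHIRCEFELKEGYIPTIQIKRSRFYKGNEYLKSSGGEIADLWLSNVDLELMKEHYDLYNVEYISG
LKFKATTGLFKDFIDKWTYIKTTSEGAIKQLAKLMLNSLYGKFASNPDVTGKVPYLKENGALGFRLGEEE
TKDPVYTPMGVFITAWARYTTITAAQACYDRIIYCDTDSIHLTGTEIPDVIKDKVDPKKLGYWAHESTFK
RAKYLRPKTYIQDIYMKEVDGELVEGSPDDYTDIKFSVKCAGMTDKIKKEVTFENFKVGFSRKMKPKPVQ
VPGGVVLVDDTFTIK
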