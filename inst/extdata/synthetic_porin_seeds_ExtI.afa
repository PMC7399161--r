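>ExtI_seed_01
IELEFDVGIDIDFDNGNGTNGNIDLNLYDEFEIELDGNSDTDSYLEFEIEVEVEFDVEDSGDTTDGVSID
IEVEVDFEADQTTGISSGLEVFMELEIDFDFDNTNTNNSNIDFELDIELDVDFESATTTTNSIDFDFDIE
FEIDMESNNNPDSGFELDIEFEFDIELDTSDGGFGSVEIDIDLEIEFEIEDSLSDNGNIDIEIELEIEVD
VENSNWYTDGIEFELELDVDIELEDTGDSDFSFDLEVQIEVDFDFDSNTSTTGTFDFELEVDIRLNVENN
SNGRTNVFVDLDKDVDLDLDSNDGTGTTLEIELEFEVELEMEGDADWDGSIEPDVELDFELDFE
>ExtI_seed_02
IELEFDVEIDIDMDNGNGTNGNIDGDLDFEFESELDGNSDDDSDLEFEKEVEVEFDEEDSGDDTDFVDYD
IEAEVDFEVDNTTATSSGLEVEFELEIDFDFDNTNTNNSNIDFQLDIELDVDFESRTTTTNSIDFDEDIE
FEIDFASSNNNDSGFELDIKFEFDIELDTSDGGTGSVEIDIDDEIEEEIEDSTSDNGNIDIEQELEIEVD
VENSNSTTDLIEFELELAVQIELPDTGDSDDSFDLEVETEVDFDFDSNTSTTGTFDFELEVIIDLDVENN
SNGGTWVEVDLDFDVDLDLTENDGDGTTLEIELEFEVELEVEGDDDSDGSIEVDVELDFELDFE
>ExtI_seed_03
IELEFDVEIDIDKDNGNGTWGNIDLVLDPEFEIELDGLSDTDSDTEFEWEVEFEFDVEDSGDDTDGVDID
IEAEVDFEVENTTGTSSGLEVEFELEIDFDFDNTNTNNSNIDFELDIFLMVDKESTFTNTNSIDFDTEIE
FRIDFESNNNNDSGFELDIEFEFDIELDTSDGGTGSVEIDIDLEIEFEIEDSTSDNGNFDIEIRTVIEVD
VENSNSTTQGIAFELELDVDIELEDTGDSDDSFDLETEIEVDFDFDSNLYDRGAFDQELEVAIYLDVENN
SNGGTNVEVDLDFDVPLDLRSNDGTVTTLEIESEFEVELEVEGDDDSDGSIEVDVFLDFELDFE
>ExtI_seed_04
IELEFDVENDIDTDNGNQTNGNIDLDWDFEFAIELDGNNDTDSDLEFEIYVEVEFDEEDSGDDTIGKDID
IEVEVDFIVDNPTGTSSGLEVEFELEIDFDFDNTNTNKSRIDFELDIEVDVDFESTTTGTNSIDFDFDIE
KGIDNESNNNNDSGFELDIEREFAIELVTYDGGTGSVEIDIDLEIEFMEQDSTSDNGVIDIEIELEIEVD
VVNSNSTTDGIEFELELDSDDFLRDTGDADDSFDLEVEIEVDFDFDSITSTTGTPDFELEVDIDLDVENN
SNGGTNVEVDLDFDVDLDLDSNDGTGETLWIELEWESELEVERKDDSDGSIEVDVELDFELDFE
>ExtI_seed_05
IELEFDVEIVIDFDNGNGSNGNILLDLDFEFEIELDGNSDTDSDLEFAIEVEVEFDVEDSGDDTDGVDID
IEVEVDFEIDITTGTSSGLEVEFELEIDFDFDNTNTNNSAIDFELDIEVDVDFESTTTTTNSIDFDFDIE
FEIDFESNNNNDSGFELDIEFEFDIEVTTSDGGTGSYEIDVDLEIEFQIEDQTSDNGNIPIEIELEIEVD
VENSVGWTDGIEFELEPDVDITLEDTGDVDDLFDLEVEWEVLFDFDSNTSTTGTFDFELESDIDLDVENM
SNGGTNVEVDLDFDVDLDLDSNDGTGTTLEIELEFEVELEVEGDDISDGSIEVDVELDSELDLE
>ExtI_seed_06
IELEFAVEIDIDFDNPYGTNGNIDLDLDFEFYIEEDGSSDTDSDLEFEEEVEMEFDVEDSGDDTDGVDID
IEVEVDFEVDNTTGTSSGLEVEFELEIDFDFDNTNTNNSNDDFELYIEGDVDTESTTTTTNSIDFDFDIE
FEIYFESNNNTDSSFELDIEGEDDIELDTADGGTGSYEIDIKLEIEFEIEDSTSDNGYIDEEIELEIEVD
VENSNSTTDGIEFEEELDVDIELERTTDSDDSFDLEVEIEVDFDFDSNTSTTGTFDIELESGIDLDVEGN
SNGGTNVEVDVDQDVELDLFSNYGTGTTEEILLEFEVTLEVEGDDDSDGSIEVDVERDFELDFE
>ExtI_seed_07
IELENDVEIDIDFDNGNGTNGNIDFDLQFEFEIERDGNSDTDSDLEFEIEVEVEFDVEDSGDDTDGVDDD
IEVEVDFEVDNDTGTSSGLEVEFELEIDDDFDNTNTNRSKLDFELDILLDVDFESTTTTTNSIDRDFDIE
FEIDFESNNNNDSGLELTIEFEFDIELDTSDGGTGSVEIDIDLEIEFEIEDSRSDNTNGDIEIELEISVA
VENSNSTTDGIEFMLELDVDGELIDTGDSDDSFDLEVEIEVDIDFDLNTSTTGYFDFELEVDIDLDVENT
SNGGTNVLSDPDFDVDLDLDSNDGLGTTLKIELEFEVELEVEGDDRSDGSIEVDVEQDFELDFE
>ExtI_seed_08
IEPEFDVEIYIDFDNGLGTNGNIELDLDFEFEIELEGNSDTDSDLESEIENEVEFDVEDSGDDTDGVDIN
IEVQVDFEVDNTTGTSSGLEVEFELEIDFKFDNTNDNNSNIDFELDQELDVDFESTTTAFNSIDFDFDIE
FEIDFESNNNNDFGFELDIEFEFDIELDVSDGGTGSVEITIILEIEFEIEDSTSDNGNIDIEISLESETD
VENSNSTTDGAESGKELDVDIELMDTGDSDDSFSLEVEIEVDFDFDSNTSTTGTFDKELEVDIDLDVENN
SNGGTNVEVDLDFDVVLDLDSNDGTGTVLEIESEFEVELEVVGDDDSDGSNEVDVELDFELDFE
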