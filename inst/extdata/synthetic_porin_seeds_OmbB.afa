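>OmbB_seed_01
VEFEVDFEFDIDFESTDDGGDTFEIEFDVDLDVELEDSDDDNGNIELDLDVKIEIGVDDSTDNDSGKDVE
FDIDLDNDFENGSTSGDNIEVEVDLDIALEFESSTTGNSYVEFEFEFEIDLEVESGQGSGSDIDIEVDVE
FDIDFEDSSGTSTFPDKDIEIEIEFDIEDSDNDDGSLDFFFDFDFDFNFEDSDTSNSGLDLDVDVIIEFE
KENNTIDGNSLDAEIDIDIEFDVEDTVGWYDTFDIDRDFDFEVDLDSDTGSDSSFSIEIELDLDIEVENS
TSDGTSFDLEFDVEIEVEIEGGGDSNTSVEIDVDIEIETDVETNGGSSTTIEEEVEIEVTLDVE
>OmbB_seed_02
VEFEVDFERFVDFEDTDNGGDTFEIEFDVDLPVEVSDSDDDNGTIELDLDKDIEIDVDDSTDNDSGVDVE
KDRDLDLDFENGSTSGSNIEVEVDLDIDLEFESSTTGLSSVEFEFEFEPDLEPESGDGSGSDIDAEVGTE
FDIDFEDSSGTSTTFDVDPEIEIEMDIKTSDNWDGSLDFEFDFDFDFDFEDSFTSNSGLDLWVDVDIEFE
FENNTNDGNTLDFEIDIDAEFDVENTNGTGDTFDIDYDFDFEVNLDSDTGSDMSFDESIELDLFIEVENS
TSNGTSFDLEFDVEIWVEIEGGGDSNTQVEIDVEIEIELEVETNGGSSFTIEIEVFIEVELDVE
>OmbB_seed_03
VEEEVDFNFDVDFELTDAGGDTFEIEFDVDLDVELEDSDDDNGNIELDLDVDIEIDVDDSTDNDSQVDVM
FDIYLDEDFENGSFSIDNIEVEKDLDIDLQFNPSTTGNSSVEFEDEFEIDLEVESGDGSGPDITIEVDDE
FDIDFEDSSGTSTTFDVDIEISIEFDIETSDNDDGILDFENDFDFDEDFEDSDTSNSGLDLDVDADIEFW
FENNKNDGNTLDFEIDIDIEFKVEDTTGTGITFDIDFDFDFFVDLDSDTGSDSSFDIEIVLDLDIEVENS
TSNGTSFDLEFDVEIEVENEGGGDSNTSVYMTVEYEIELEVETNSGSSTTIEIEVEIEVETDVE
>OmbB_seed_04
VEFEVDFEFDWDFEDTDDGGDTFEIEQDVDLDVELEDSDDDNGNIELDLDVDEERDVDDSTDNDFGVDVE
FGVWLDLDFENGSTEGDNIEVEVDLDKDLEFESSTTGNSSVEFEWEFEIDLEVISRDGSNSQIDIEVDVE
FDIDVTDSSGTSTTFDRDIEIEIEFDIETSDNIDGSLDFMPDFPFDNVFEDSDTSNSGLDLDVDVDIFFE
FENNTNGGNMLDFEIDIDIEFDVEGTTGTGDTFDIDFDFDFEVRLDSDTGSVSSFDITIELDLDIEVENS
LSNGTSFDLEFDLEIEVEIEGGGDSPTSVEIDVEINIELEVETNGGSDTTIEIEVEIEVELDVE
>OmbB_seed_05
VEFEVDFEFNWDFELTDDGGDTFEIEFDVDLGVELEDSDDDNGNIWLDLDVDIEIDVDDSTDNDSQVDVR
FDIDLDLDFENGSTSGDNAEVEVDLDIDLEFESSTTGNWSVEKEEIFEIGLEVESGDGSGSDIDIEVDVE
FDIDFEDSSGTSTTFDVDIEIEIEFDIEPSDNDDGSLDFEFDFYRDFKFEDSDTSNSGLDLYVDVDIEFE
FENNTNDGNTLDFEIDIMIEFDVEDTTGTGDTFDIIFDFDFEVDLDSDTGSDGSFDIEIELDLDISVENS
TSIGTSFDLEFDVEITVEIEGGGDSGTSQEIDVEIEIELEVLTNGGSWTTIEDEVVIKVELDVE
>OmbB_seed_06
EEDEVDFEFDVDFEDTDDRGDTFEIEFDVDLDVELEDSDDDNGNIELDLDVDIENDVDDSTDNDSGVDVE
FDIDLDLFFENGSTSWDNIEVEVDLDIDLEFESSTTGNPSVEFEVEFEIDLEVESGDGSGSDIDIEVDVE
FMRDFEDSSGTSTTFPVDIEIEAEFLIETRDEDDGSNDFEFDFDLDFDFEDTDTSNSGLDLDVDVDIEDE
YYNLTNDGNTLDFQMDIDIEFVVEFTTGTGDTFDIDFDFDFEKDLDSDTGYDSSFDIEIELDLIIEVENS
TSNGISEDLEFDVEIEVEIEGGGRSNTSGEIDVEIEIELEVETNGGDSTTPEIEVEIEVELDVE
>OmbB_seed_07
VEFEVDFEADVDFEDTDDGGMTFEIEFDLDLAVELEDSDDDNGNNELDYDVQIEIGVDDSTDNDSGVDVG
FDIDLDLDFENGSTSGKNIEVPGDLDIRLEFESSTTGASSVEFEFEFEIDLEVESGDGSGSDIDIEVDVE
FDIDFNDSSGTSTTFDVDIEIELEFDIETSDNDDGSLDFEFGGDFDFDFPDSDTANSGLDLDVDVDIEFE
FENVTNDGNTLDFEIDIDIEFFVEDTTMTIDTFDIDFDQWFEVDLDSDYGTDSSFDIEIELDLAIEVENS
TSTGTSSDLEFDVEIEVEIEGKGDSNTSFEIDVEIEIELEVETNGGSITTIEIEVEIEVENDVE
>OmbB_seed_08
VEFEVDFEFDVDFEDFMDGGDTFIIYFDVDLDVVLEDSDDDNGIIELDLDVDIEIDVDDSTKNPSPVTVE
FDIDELLDFENGSTSGDNIEVGVDLDKDLEFESSFTGNSSIEMEFFFEIDLEVLSGDGSGSDVKIEVDVE
FDIDREDSSGTSTIFDVDIEIEIEFDIEQSDNDDGYLDMEFDFDFDFDFEDSDTSNSGLDLDEDVDTEFE
FENNTNFGNNWDFEIDIIIEFDVQDTKGTGFTFDINFDFDFEVPLDSGTGSDSSGDWEIELDLLIEVENS
TSNMTSFDLEFDVEIEVEIEGGGDSNTSVEIDVEIEIEVYVETNGGSSRDIEIEREIEVELDVE
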