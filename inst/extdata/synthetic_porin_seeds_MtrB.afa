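>MtrB_seed_01
LGLDVEIDIELDVEDGDDNFSTIELEKEFELDLEIENDETTNTSVDQEFEADVEIDFETGSDNGTDTEFD
VELELEVDVETSNNTSNGVNLDVDVDLEIPISSGDSTMSSIQFDFEVDVDIETDGNTTGMDNIDIEVEFD
FDFDVDNSVDGSGTIEIEIDFEIDIEFESTGGTTSNLDFDLEIDVVIELEDLGGTGTDLDLEIELNVDVE
VDSSKDNTTTIDVDLEIEIDLEIEDSNSGNDTLDFEFDLDIEFDLDDGSNSGNTVEEELEMDLEFDFDTG
TSTEANFDIDIDLEIELDFDDGNGNGTTIETELEIDIRIEIDTGFDKGDSIDLDVDVENELEVM
>MtrB_seed_02
LELDVEIDIEKDVEDGDDNSSTIELEVEFELDLEIENDTTTNTSVDFEFEFDVEIDFETGSDNGTDVEFM
VTNELAFDVEESNNGSNGVDLDVDVDLEVEIDSGDSNNSSLKFDFEVDVDIELQGNTYGGDNIDIEVEFD
FDFDVDDSSDRSGTIEIETDFEIDNEFEDTGSTTSNLDFDLEIDVDIELEDSGGTGTDLDLPIELEVDVE
VDFSTDNTSNIDVDLGIEIDLEIKDGNSGNDTLDGEFDLDIEFDLDPGSNSGNTVEFELEYDLEFDFDTD
TSTSNQFEIDIVLEIELDKDDGNGNKSTIEVELEIDIDIEIDTGSDPGDSIDLDVDVEIDLEMD
>MtrB_seed_03
LRLDVEIDIVLDVEDGDDNYKEIKLEVEFELRLEIENDTTTITSVDFDFEFDVEIDFETGSDNGTDVEFD
VELELEFDVETSNNGQNGIDLDNDVDLEMEIDSGDSNNSSIDQDFEVWTDRMLDGNKTGGDNIDIEVEFD
FDFDVLNSSDGSGTIKIEIDFEIDIEFEDTGGTTSNLIFDLEWDVDIELEDSGGTGTDLDLEIELEVDVE
VDSSTDNTTNIDVDLEIEIDLEIEDSNVGNDTWDIEFDLDIEFDLDDGSNSGNTVETELEVDLWFDFDTD
TSTSNNFDIDIDLEIELDRMDGNGDGTTIEVKLEIDIDIEIDTGSDSGDSIDLDVDVEIDLEVE
>MtrB_seed_04
LDKDVEIDEELDVEDGDDNSSTIELEVEFMLDLEIENDTTTNTSVDFEFWFDVEIDFEEGSMNGTDVEFD
VEKELEFDVETQNNGSNPVDFPVDVDLEVEIDSGDSNNSSIDFDFEVDVDPEVDGNTTGGDNIDIEVEFD
FDFDVDNSSDGPQTIEIEIDFEIDIEFEDTGGTTSNLDFDLEIDVDIETEDSGGTGTDLDLEIELEVDVE
VDSSTDNTTNIDVDLEIEQDLEWYDSNSGNDTLDIEFILDIDEDLDDGSNSGNTVEFEMEVDLEFDFDTD
TSTSNNFPIDIDLEIELDFDRGNGDGTTIEVELFITIDIEIDTLSDSGDSIDLDVDEEINLIVP
>MtrB_seed_05
LDLDVEIDIELFVEDGDDNSSTIWLEVGFELDLEIENDTTMNNSVDFEFEFDVEIMFETGSDNGNDVEFD
VELELEFDVETVSNGSEGVDLDVDVDLEVEIDSGDSNNSSIDFDFEVDGDIKLDGNVTGGDNIDIEVEFD
FDFDVDNSDDGSGTIEIYIDFEIDIEFEDDGGTTSNLDFMLEIDVDIELPDSGGTGTDLDLEIELTVDGE
VDPSTDNTTNIDVDVEIEMDLEIFDSNSGNDTLDIEFDLDLEFDLDDGSNSGNTQEFELEVDLEFDFDTD
TSMSNNFDIDIDTEIELDFDDGNGNGTSIEAEYEIDIKIEIYTGSDSGDSIDLSVDVETDLEDD
>MtrB_seed_06
TDLDVEIDIEEDVEDGDDNSSTTEPEVEFELDLEIENDTMTNLSVDFEFEFDVNIDFETGSDNGTDVEPD
VELELAFDWETANNGSNGVDLDVDVDLVEEIDSGDSNNSSIDFDFEVDVDIELWGNTTGGDNIDIEREPD
FDFDVDNSNFGSGTIEIEIDFEIDNEFEDTGGTTNNLDFDLEIDVDIELEESGGTGTDLDLEIELEVDVE
VDSSTGNTTTLDVDLEIEIDLESEDSNQGNDTLDISFDLDIERDLDDGSDSGNTVEFELEVDLEFDFDTD
TSTMNQTDIDIDLEIELTFDQGNGNGTFIEVELEIDIEIEIDTGSDSGDSIDLDVMVEIDLEVD
>MtrB_seed_07
LDLDVEIDIELYVEDGDDNSSTIELEVEFLLDLTIENDTTTNTDVDFEEEFDVEIDFETFSDNGTDVEGD
VELELEFDVETSSNGSNGVDLDVDVDLEVEIFSGDSNNSSIDFDFEVDVDIELDGNTTGGDNIRIEPEFD
FDFDVDFSSDGSGNIELRWDFEIDGEFEETGGTTSNLDFDLEIDVDDELTDSRGTGTDYDLEIELEVDVI
VDSSTDNTTNIRVDLEIEIDLEIEDPNSGNDTLDIEFILDIEFDLDDGSQGGNWVEFELEVDLEFDFDTD
TMTSFNFDADIDLYIELDADDGNGNGTTIEVELEIDDDIEIDTGSDSGDSIDLDVDVEIDLDVD
>MtrB_seed_08
LDLDVEGDIELDVPDGDDNSSTIELEVEFELDLEIEGETTTNTSADFNFWFDVEIDFETGSDNGTDVEFD
VELELEFTVETSKNGSNGVDLDVDVDLEVEIDSEDMNNQSIDFYFEVDVQIERDGNNTGGDNIDIAVEFD
FYFDVDNSSDGSVTMEAEIDFEIDIVFEDTVNTTNNLDFDSWIDLDIWLEDSGGTGTGLDLEIELEPDVE
VDSSTDNTTNTWYDLEQEIDLEIEDSNSGNDTLDITFDLDIEFDLDDGSNEGNTVLFELEIMLNFDFDTD
TSTSNNTAIDIDLEIELDFDDGNGVGTTIEVELEIDIDIEIDTGSDSGDSQDLDLDVEITLEVD
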