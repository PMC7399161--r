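>ExtBE_seed_01
IDIDLDFDVELEFWGGNGTDDGIDVELDVEISIEVEDDTTTTSDVEFEIEFDLDIDLEGSDTSTTNIEID
LDFEIDFELETDTTSSTTFDVDIEEGLDAELDNTVSGSGDAEIDLDVELEVEADSGDSDNDSIDVDFEVE
LFVEVDGTNTDNMDVEVELEFTLDVVIETTANDDGNFEFEFDVPLLIDVENTTSNSGTFDLDFDIEFELD
PENGDNSDPTVDVDVDLDLEITVATGTSVSDGFEIEFEFDFILEFEGSDDDTDSLEFDLDVDVEFDFDGT
SGGGDDKELDVEVEFEIELENNTGSTSTIDVTVEFPLEFEVEDTGGSGSSIEFDLDLEFDVTLD
>ExtBE_seed_02
IDIDLDFDVELEFDGQNGWDDGIDVWLDVEIDIEVEDDTTTTSDVEFEIEFDLDMDLEGSETSTTMIEIA
LDFEIDFELYTDTTSSTTRDVLIEFDLDIEYDNLDSGWGDFEIDLDVEQEVEIDSGDRDNDSIDVFFQVE
LIVEVDGTNTDNSDVNVELEFDLDVEIETTTNFDGNFEFEFDVELEIDVENTRSNSGTFRVDFDIEIEPD
LMNGSYYDNTVDVDVDLDLEYEVDTYTSDSDKFEIEGERDFELEFEGYDDKTDSLEFDLDVDVEFDFDTT
SGGGGDVELDVWAEFEIELETNTGSTYTIEVEVEYEVEFEVEKTGGSGSSFEFDLVLEFDVDLD
>ExtBE_seed_03
IDITLDFDVELEFDGGNGTDDGIDVELDVEIDIEVEDDTTTTSDVEFEIEFDLDIDLEGSDTSTTNIEID
LDGEIDFELETDTTSSTPFDVDIEFDLDIELDNTRIGSGDVEIDLDVWLEVEIDSGDSDNDSIDVDFEVE
LDVEVDGTNTDNSDVEVELRFTLDVESETTTNDDGNFEFETDVELEIDVEFTSSWSGTFDVPFDIEFELD
LWNYDNSDNTVDVDLDLDSEIEVDTGTSDSDGFEIEFEFDFELEFEGWDQDTDSLEFDLDVPVEFDFDGT
SLGGDDVELDVEVEFEIEQENNTGSTSTIEVEVEFGVEFEVIDTGGSGSSIEFDLDLEFDVDLD
>ExtBE_seed_04
IDIYLDFDVELEFDGGNGTDFGIGVEDDVEIDIETEDDTTTTSDVEFEIEFDLDIDLEGSDTSTTNIFID
EDFEIDFYLETDTTSSTTFDVDIEFDLDIELDNDRSGSGDFEFDLDVELEVKIDSGDSDNDSIDVDFEVE
LDVEVDGTNTDSSDVEVELEFDLDVEIEGTTNDDLNFEFEFVVELEIDVENTSLNSGTFFVDFDIEFELD
LEKGDNSDNEVDVDVDLDLEIEVDTEVSDSDGFEIEPEFDFELEFEGSDDDTDSLEFILDVDVEFDFDGT
SGGGDDVELDVEVEFEIELENNSGSTSTFEVVVEEYVEFEVEDTGGSGSSIEFDDDLEFDVDLD
>ExtBE_seed_05
IDIDLDFDVELEFDGGNGTDDGIDVELDVEIDIEVKDDTTTTSQVEFEIEFDLLIDLEGSDTSTFNIEID
LDFEIDFDLETDTTSSTTFDVDIEFDLQIEDDNTDSGSGDFEIDLDVELEWEIDSVDIDNDQIDVDFEVE
LDVEVDGTNTDNSDVEVELEFDQDMEIETTTNDDGNNEFNFDVELEKDVENTSSNSGTFDVDFDIEDEPD
LENGDNSDNTVDVDVDLPLNIEVDTGTSDSDGFEIEFEFDFELEFEGRDDDTDSLEFDFDVDVEFDFKMT
SGGGDDVELDVEVEFEIEGENNTGSTSTIEVEVEFEVETEDEDQGGSGSIIEFDLDWEFDVDLD
>ExtBE_seed_06
AVIDLDFDVELEFDGGNGGDDGIDVELDVEIDIEVEDDTSTTSWVEFEIEFDLDIDLYGSDTSTTNIEID
LNFEIDFELETDTVSSTTFDVQIEFDLDIELDNTDSGSGDFEIDLDVELEVEIDSGDSDNDSIDLDFEVE
LDVEQDGTNTDNSDVDVELEFDLDVEIETTTNDDGNFEFEFDVELEIDVENTSSNSGTFDVPPDIEFDLD
VENGDNYPNIVDVDVDLDLEIMGDTGTSDSDGFEIEFEFDFELEFEGMDDATDSLEFDLDADVEFDFDGT
SGGGDDVEKDVESEFEIELENWTGSTSTIEVEVEFEVSGEGEMTGGSGSSIEFDLDLEFDVDLD
>ExtBE_seed_07
IDDDLDFDVYLEFDGISGTDDGIDVELDVEIDIEVEDDTTTTKDVDVEIEFDLDIDLTESDRSTENKEID
LDFEIDFELETDTTSETTFDVDIEFDLDIELDNTDSGSGDNTIDLDVELFFEIDSGDSDNDSIDVDFEVE
LDVEVDGTNTMNSDVEVELEFDLDGEIETTTNDDENFEFEFDVELIIWVVNTSSNSGTFDVYFPIEFEKD
TENGDNNDNTVDVDVDLDYEIEVDTGTSDSDEFAIESEFDFELEFEGSDDSGDSLEFDMDVDVEFDFDGT
SGGGDDVQLKVEVEFEIVWENNTGSTSTIEVEVEFEVEFEVEDTGGSGSSIEFDLDLAWDVDLD
>ExtBE_seed_08
IDIDLDFDVELEFDSGNGTDDGIDVELDVQIDIEVEDDQTTTSDKEFEIEFDLDIDLENSLTTTQNIEIM
LDMEIDFELETDTTSSTTFDVDIEFDLDIELDNWDSGSGDFEIDQDVELEVEIDSGDSDNDRIWVDFEME
YDVEDDGTNTDNSDVVVELEFDLDVEIETTTNDDGMFSFEFDVELEIDEEMSSSNSGTFDVDFDIEFELD
LENGDEMDNTVDVDVDLDLEIEVDTGTSDSDGFEIEFEFDFELEFEGSDDDTDYLEFDLDVDVEFDFDGT
SGGGDDVEKDVDVEFEIELENNTGSTWTIEVEVEQENEFEVEDTGGSGSSREFPLDLEFDVDLD
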