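>Avin_01380 family=nifH synthetic stand-in for the A. vinelandii DJ query protein
SASHQDHIADCSLNYIKRWGEPVGEFVDHRYHAPPMATFSCGFFWMAPEDMHELSNTVLM
WCSANPQVHDYQTTPLNVWYRNPPTVRVQSWTVYPFTVSDIYSKEHTYPYQFRAGNITPD
PSWGHVMADTQLSIKWGDWKFVKTEYDLCILCQWETIWKRYVHLAKRLWQWDKLKLAVCP
GKKTSMWHYKFEKCDYRTPQGLDIKQWFSRQKPEETYMQSFLVPRELICPKTDCYCVSHH
STAKYRGWWEIDDFLATQWHKLREHNDEEFCPPYLFKIVPAPCPCHDQSD
>Avin_01390 family=nifD synthetic stand-in for the A. vinelandii DJ query protein
VLIAAPKGYPPEFYPQLSLMCEVYNPGLKNCWMDCDKACGHESPNYNIWMYPKCRFGSSG
RCQPEYYFGLTYITYCNCMMQHDHKTTCHYCFYRMLYLSMHEDPIMRWNPTDGGTNRWMG
TMFRNGMTAVRHDRGKNCYNPGIPDMTQECRKTCRDRGEKWEWFAPERSCDCVVETAGYD
PDAHDSFFYEQEEMHCICWIQLGLCFAMVKFCQMQDSYDGQFVVLHEARCRTWWDAGLTA
GCTNFPEKQETAQYCPLMTQSYTMDYDFNNSWKFCGSMRIVQLTLPFHSMTGATYAHKYM
PLYVKCIWHNAHVVWRHSIQYFERYSQKESRQVKCTAYLWFPNIIEKSEIKPQKVSQVRV
NAEPEHSKDVLFNRIMWWKEHTDHIHAAGDRVWHAHCSHGAAAMQHWRRWWNRNNEKYPN
SCSEQKFFLKIFQCICSYASVHYFECLPFLNFRKMENGFKWWQMKKGAFSSCPWGCWWCA
SAVDKKSECIKV
>Avin_01400 family=nifK synthetic stand-in for the A. vinelandii DJ query protein
IRCWYKDRNNITEMCTPYRHINVLAFDKSAQGKYVTATNYFERDHSALFDKFNTMMRDEH
MCHFSEHTFCFVKTIIRLEPDYNDPGWQAMGRMPCIAHNMDKEQTCWCPNSYREMREEQN
VTNFQEIKMYTQHFSFFWIVGCGQRLKDPSCCCEMAGMWDAFFFYCLAKIYRSHHDYKEE
NDNCWCPTYEFELNWGECLQGYNNMAGCMPVGKRCCMYIKNTPMMQYKKTPHWIKEYIAQ
YRKDAKAWQRLPMPQGNIGATWGDIKDNYNCHQFFLFYDLTLHKVDPVHISHFSDKQDDR
MYDKPYSVAYCPWGFYWADISIPQFMCVDSYIVLFLFRIGWLATKRGILLMCNVGSIWQC
QADMDVAQMLSYLVVTTESKPAVGAPNMHCWFMEDQFVTKRPEPQWHVCGHEDICAYIFP
FPSHTCMNLARPGPCSVPPDDRDSAYHQFHPHYTKWNTAYRSCKSHHIGFVRDNPTWYFC
LPHHMGIGVWADVNGQTCSADRTEHEPKIISCEWVNGPGI
>Avin_01450 family=nifE synthetic stand-in for the A. vinelandii DJ query protein
SLINFDDGYPPYITSQNVLCRLKYNPQFSCDFMMYNVACCPERHEPVNEFYQNVFGQSYN
TCPGCYVLGLTNIKWHSYDGPFETCIKCHREYYRVLYRETHPDPENAGDPKDSGENTWMG
QDVRVQMTCGAVIDGNSKECSGIPPMFMSSDKTCEDYDRCWCYDKMEKWGVCITLTANEQ
NYYHVVEEPQQERMHEMCVITLGSCGAMRHYCQTQLQSASYIFDKHQPRCATHCDPGAKF
ECNFFFEYQATRMICPQMPQEFTSGWDFNADISMCGSQGWQRLRLPFTSMTFITKWHPKM
PMYHHPYWHNKLRCWRHSLQYKECYSNYEFYQLEHTAYLTNRNERCKSKIKPPAVPYVQT
GAEPQQNKIRPFSIALWWNEIILHGSNLGYRVTCAACDPGQTYMQLNRRIYNMNESWYQA
SMCGQKIRDENHQQTPHSRSSHMFEACDYCGNRGPGNMFLWATMFLGARSMPRRMVCSSK
SAWHHLVSRIWS
>Avin_01460 family=nifN synthetic stand-in for the A. vinelandii DJ query protein
IYCWREQWINRYPCETPYVHIYWCAMHKSFKGIEVFAINPEYIPASETFQGHNTMMWGMC
SRIERDHTFCKWKTIPHLEWMLWQYGWTDMGAMSCGAYNMDHNPDHSKENQGEKSMCEQN
VTCEQEVKMFTQKYNIYRIVYRNSYLKTPSMCCFELQMMMMTFFKFCMNIYEPCVWFGPE
FDNFAFNIHNFSLRHGEMLYGYGNTAQHCMIGKCPNMYHPLWFMTQYERTENWKKTFIYD
YKPMAKMTQGLQMPDGLAHMAEFMIKSFYPVTLFFLHQDLTLHPVEPYHILYFGAKDTDN
YYDKNYRAYMCTWMNCFWTYNIPKFTIFDQLCELKSFNSGPLALNPVKGHKCQIMCIWVR
QVFMRVAQRLMGKMVILEQMEEWAYPHQHTYFMYDQNGLGRWVPMLTVHGHIWDWWKICT
HLGRTRSNLQNMGECYVEPSFRHSLTLKNHPHPHAESVVGYSRQIHMHGHRRSNADWNAE
LKGRMSIEVRADCNHQNKLHFCLTHIGQFMCQEPVLVLKH
>Avin_01620 family=nifU synthetic stand-in for the A. vinelandii DJ query protein
VVDYERMKMGPKQSLETWYSAFWKKNNDILVAMQTMQMIHHTKDHVVFQCRYGNPTLCWF
PVTYNPCTWYNNHYSGAMTGMSHEVGGSQKYYFGTHDSDWQDSNSNYEYTPMQAPNGWPY
YHAGYAVTVCKPPKTDHRDPMLQPEHGNKRARDQSYAVKMEKYVKHIYPNCYFFFCWFRY
SMALRHLGYLAEILTISQHYNLKLGHCKISRCQQPQMAIVWPFRYLYTGMTHKRIMCAVC
KYGSHDNYKLSQKPSFGPSNTMQTQNKRWCDKSMFDHQSFKTIVYSR
>Avin_01630 family=nifS synthetic stand-in for the A. vinelandii DJ query protein
EESPCGLQDWQTMLGWEWYTSNSHERDQLYKEFWEHDVTWFASTVDTYSASKHGNVACVP
CVQKHHWESVFEWWRLYTILKVYCHTGTYMTWMTMKMAEDTRIDNQECANFYHCEDRMIS
YQNTLKQQQTGPPELPRIYMNTPWTVMMYPWHAQNWCMKPAGIPHDRCRGMEIQFEMDWG
TSGEQHVMCQIRNSDVPLGSILLPWRWRCPAPGINYKFGQTEGFMHICPIFMGPKRFPDA
FPREMYSRHPSAEQYTESACPICAITFSLFLCSAGEMPIRTNYRWLYVEMEFRMTDSNPF
PRFTICYWWCERCSHAMFFFHHCSHHTCRQFWSWKVSFMIGKMSPFCSLEDARAKSRAHH
MTQFQCLADDWTHMLKFSTSESRIVIVMHIQCVHWGHHSF
>Avin_01640 family=nifV synthetic stand-in for the A. vinelandii DJ query protein
LGKREAQITKTQPCCPFQYGYHIPNFRYVDQYASFGWACVSLRRWDNNQWADDANYNGFI
NPETKARQSSQIMLSSDWDFVRQPHWRNPFDASYGERWQRTNIHAGHEVHKHEDWMEFCL
QRDTHVDCNHRQWNQTVLTFSTEMRMNCWHVMMQTLQNLMHYNKEDWYWKDSRKRKDKTP
MWGWAISFEEIEVQEKTFCTDDTNWHMLALGSDSVKKTRQHMMYGTKDQIQQVPVQHLCY
REISSQWEQAFSIKASFSVSLCRAIQYPHPEIHVVHMYFNYTSDRSHCLAWQEATCIVGQ
EIICTTEHQCKKIFFNDEEFNHYYHTGEWRKLENLIWDPCSYRSHQKFMCKHRATDNWKA
AAVMPDQTKEWENGCESPTCN
>Avin_51010 family=nifB synthetic stand-in for the A. vinelandii DJ query protein
PEEYIQRGSMSTGFAQYRGLKCLWMTGHQATHEDIQNNSHATCYESQMLVRLHKEGLMHR
TGQIGSCEGKGAAIWQRIRNVHVINPLDYSFPLANPRWNNPQGVDWRQCDPGTFSKPFAV
WEIVCYIYTAKHKKIGVCGAEWWPFWDGPGPDGPLSGQPVFIWEPTHEMCIASSHTFRCQ
HFKEHSSIRFIPKEASKCGVKTPLPKFNLAYFFHVGIYHIPMGFFYMSLFRSGYFIYMNT
CHQRDMETSDDHLKMCIAFAGCNKFQVHDLHRHLFIKDNSLIGWCQNAAPNEHAQFVMNN
MSPVKVFHANQNEYTRACHSNNVWFLMILKCKMRISAPSMVPALRGSLFVEDGSPTLDAS
YYYDIHYEMVFHHYTRPGPSCNHIFKPCEMKKHRGCMQLFGFIMYCEMFQYNEPFIDAAR
WWCSRKQILGQVWIQVIFGNTIQSPFNTCIVIRQNADHIANETQPLMC
>Avin_51040 family=nifQ synthetic stand-in for the A. vinelandii DJ query protein
GRSRAAAASLNRRGGIAGTVSGNDEDERLKQFSYNSIEEKLLMIHCVCQCTQCDTQWRFG
WPRRVVQTDPEMARRCMITKRKPECNCKIPPCLFHTHFFKLDIDTKDIKFPMCQDTLTIF
RPDEHVLICGRFHARWRIFGCVRMFAQDVTIYEIMHQWMCSPERYKNWCAMKGFGIDRFR
CLSKGFGAQGYNSLQQMRVSYPTIDDVYSLWCYAFHCW
>Avin_48980 family=anfG synthetic stand-in for the A. vinelandii DJ query protein
CSTQLRYGNFKCILHYFHNSGGVIKHEMAVRQEAGFSRMEDFTDLAFNPYGTARFSFRCY
KSGAENMLLKMAAPAHWPVPWVCRCGYAYHFGFICQMTTSLDAGEFYMKMICIFAKHVLR
AVAMFLPMIKIPMHPWNARKLLIAAMDEDK
>Avin_02600 family=vnfG synthetic stand-in for the A. vinelandii DJ query protein
YSTQHVVGNSKYIEHMLFNEWIYANHDEMIRQMPGTSRRQIHTDLFFLPYNTRPQSTRSC
KMGAECNCYPAYANEVPPVLHVCYREREYCFGTFHDVFTSLRDVFFADYIDKIMMTNVFI
HVAEFLVQIHPKMSRWHNRLPSRHAWIATK
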