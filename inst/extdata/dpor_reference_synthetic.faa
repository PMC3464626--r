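>AAT28195.1 family=chlB synthetic stand-in for the DPOR reference protein
YRCADSHYNFIKEMCSGDRKIYQLRYDKSCEITFKDPMGYFESGDSELQQKTNDGKRSKV
MCGSGFNMLAAVHTIAVIDWWYFDPQMQAIGSQLAIAHQLKMGIGWWSPNYIREERELQF
WVNAQEIKLTVQPEWAFPGMFHVQVVFDPKCYAEKFRMMAAEFSYCLAHICDSHCDSREE
NDRSCIPTFQSEMNQGCDGQIYLSRWGPSPGLQWHATYWKWFLDMQYHKTMFRIKFCHTL
YVPDAMFKFKCPNPIFRGWSTWFKAKDNYLCDCKFLFYDLTFKKMDYVHIAHMSSWQDNR
MYDMPYYYNAPWKGLYRASISIITEMQVVCYQVCCMYVPTWVEDKRACCQMSNLVGTWPM
PADPDVAQGLSWKVPRTFRKHFVFAPLDHCWWDRDVTHTYKPKCKWTPQGHKDKWAYMFF
FASRTVYQLIWVRGCSGKPDHDISVYHKGHPEKTEWCTASHNDKSHNIITDYDTNIHYVY
TPYMDNLGVEADVPGDLCAALLLEGFPEIQSKEMVKGDVI
>Q3APL0.1 family=bchB synthetic stand-in for the DPOR reference protein
HRCADSHYPFIIEMHWGLRKIPQYVYDKSCLQTGCDPLFIDESPDSMLHQVTQFGKRNKV
MCGDGFNMLAIRHTNAWIQLWYFWPQMQWIGSQLAIWHQLKNGIHWWSPCKIITQRLLFY
WVNAQTIKPNNRPCWAPPGECMVWFVFKPQCNAEYFRMAAASFSLCLGHYSDLNCNRRVE
NDPSCYPTFQHEMRRLCMCRINLSPWSPSPALGWHATYDKWFRDMLYHFIYVRIKWCHTL
YVPGVMKKAKCWNIDFRGGSVWFMYSSFYLCMCKFLFYAVKFVKCPIVKYAHMIGCPRNC
VYEFSYAYNAVWKGDYCASIPIIQEMQVVCYQWCHDYQTQQNEDHRASCQYWNLVGTRPM
LADPDVAQGLRRICPSCFRYHENFAILDHQNWKRDVTMDTPPECKRTRQGVKDGWENMFF
FPSRTYWELEWCRHCSGKPDMDTSVYWKKHPEQQEWCTASHHDSRINPITCYDTNCHYDR
FPSMDNQGVEADVPIDECAANFLERWWEKQCKEMRKGDLY
>AAP99591.1 family=chlN synthetic stand-in for the DPOR reference protein
VIIALRDGYPNAYIYQMSNMCWHYAPGHWNCWLDWDFAQVINSPGFNIEFYYSKWIGHSY
RAQWAMYEALLWIFRCASMMYHDHKHTAWICHMSREGQSMHCPYIVIFNQWCAGTSRWTF
LMDANGPSCVRHFGTKNCYNPCAIESTQQGQKTATDDMEHCHWCYDERSCCDRPAIISYN
YDAHDWTLLIQQLSHCRHWTSLGWGSFMVKFGIQEHPYFGMFHCQHIIRLRSVWEQGEIF
NCPNFPEPCATWHYCHLVTKLYPMMYDFKKSMHFALSKINGQTTMEMSWSCSYSYWMKER
NARVKDNALNCLVNWRNSPHYRDRYKDKRSIQYGWSAEQAVPPKIRKSEANPWKPFQVAT
DAWKENLVGNMPPFIHACYHRTGHDHFYWDKLMHCMCHRCAYICWHGRGNWNPSNPKGLQ
SRWAMKFFLQPIGFACFDANVAWLTCSDSQNFFKMWCHFKWPQMKKGKQSFCPLGIGWIR
VYLDKKSECRGE
>Q3APK9.1 family=bchN synthetic stand-in for the DPOR reference protein
VIIDLGNAYVVAYIYQMSGMCWCYAPPTMDIWLMYDMAQVINSRGFNLMFYQVFCRQPSP
RALAAIYEKLLPIPAFASMMYTDMFHTARICHMSHEGQSTHCDYIILNNYWCTVQSRPQF
LMDATFDSCVRKFGTKNWYLRCNIDSTGTNQKFAEHHSEHCHNNFDERSCCELPAVGRTN
YDAHMHTWLGQHTSHCRMATSLGCGSNAVSFGISEHPYFCLQHLVHGDRLRKEWWAGEEK
CPPIFPEPCATWHYKHRVTKLWPMMLDWKKSMEFALINIQDQTTGEMSWSCSYSYLMKER
NQVVKDNAENCFPMWRNSHWYGDRAKDKFLINCSWSGKQWPWPKVRESEANGPKWNQVSW
DEHKWALVGNQEQAKHMCKEATGWIRQWPDKQAHCMCHRCAYICWTFCGGWIPSNGKGCQ
SRWDMKIFLQPIWYQCFFANVAWLTCHLSQNFFKMLCHFIWMSMKFGKKSYRALIIGLIR
VYADKMDECRGP
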