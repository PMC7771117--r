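>RyR
MVKSVVHEPALSHRSRAGFCSHSHFLCVCPRGRNRYTCPELVSGSRRLTPHGRCSEPHTSTPLSACFVLV
TCVIGVPCYPTPIIMAWPWPLTLPFPVRSTVLPLLGQAHRWRGEVQERSGGLYPDKRRFKHGKDIAGGRD
SIGSLASRGGLRDAVVDSRQGNSRYHVLLFYLPLGNIRRSLWSRSGSLIFRRAMHRISGSHIRTHQGVVR
GCAADVPRSRMVRRNGTFRSALYAILLRGYVHLEHHKQFPLPRFANDKEMWAIVAPMRRDTRIHWVSTVV
GSERAHQKKYLQGLLHSTSLLGFLQSLDLNRLGPSKHGPVIVDMNRTPATATEQSSFTTPPQKPERVRVQ
VHNFQGLANLGSASRTTACKRACKTSQLRASYAHGAWVGFLVTGKCTEVPRYPQKCGCPSTCRASTPCIS
MSCSSSVLSGRLLQIYEQRSCAVYLCAIEYLPAGVFCTLFICVSSHTVSILPFSLFHAFVMQSSHLFLVR
KRRSPRSLLESVEMHYSLIGNKLPGVVVHPVGDLFEPGRAIPWKFRRQAERTHERFSSYTWSNENLCPFT
SPLWDWRTVATLDLQSGKQEVSIPCQRISHFGDVGSPSFSRVRLVRVVLFNDWNDPIRIGWVPHEVRLPC
DGFPGCFSLGSDPVACRRPVIPRRAMSLFSVSYILNYRQVQHDLVSCIGHGLLVILGLIYDYTSVTGPGR
WAPDDGPCLTFADVNKDFERAAELGQSCLEQSIHTATSAASTTSGQFIHVSPTKKAPPFQVVSYCGIVVG
FGPSITNLVFRLEGIVLLPVLAVLPRDLNVSQIRSRHRILIMRYFRDEAVLSMPPNVPHAPVAYRLETAQ
WYFTETYVTRWGRTVTACSRLRAPYGPGMPNLLDRSQCAQSRNLSFMGGTDAHAGESPYLTDNAKRLRRA
IMHGISLVYKVNLELQKLRANAVSDFGESVRNSRYTPPVTSGSILPSLFIRSPHNSTGRKPRSCGSLLLK
CCSSLPTSLVVFPVPKYTVLRLSLSSTETYEGFRVGVSARDATAWPGVVAYAYSMVGYRLQDRKGKIHLL
LQVRVGPFPSPLRRRVRPSLPKGAPVGGVKMKGAIDSTDYINTDVLATNFVHPLAASNEMGCTCPNPHQP
GIIIVSSLQRHGIYKHHSADFPKRRPHPIPSTNIHDPQTCRASRHVPLALTSPYCRVILCITLRPGCQTH
YSFPHATKSWYTATMDQEDATEEPATQVNKAFDDDEGGIYNFVEKQSPDRLTKVSRSLHNGSHFTWGHHL
LSNHRVEFGFVATWVSRSRPRIPWSVCLTTVNITVCRDYAAGEGNEKLTTPSSNISPFTTRRIRECHNPN
RAFSVRPRQKRSFLSYPPPDETRIYTPAIQSRIRFDRIRSLSARAWEIDHCRHEKGSTFRVQQIKLCCAS
FAIENKRLLLGGSLSTWRGVFHSVSMIVKILVIVDLYTPSISRRRQLSQPRLRALLQLKICGSQIFIPLQ
LLLSSHTGMPPRLSRTPPWARYGPRLYHTVCSPWYGRCCHVPQVRVPFCCNQSPILELKLKVCLVRSVMG
PCPTASLLSTSERPRWVYAASGFHIVGCMREALNFIMTVLAWWGTIKPHRSRAGTWIIHCIPPLRPWRIG
RTSDDYTPYPFGPVDVNIIPPQIANESAESTSGCVGRQSNPPVFYSRFVITTMYERIPLVEKPLHMQRDK
STQALYISPPIACAEYMSVISDVLELKLPLVLSIVGCNMTRIRQPHSNGAADMRITVSPYTGVYVDRLVV
TAAKGPRGNLPVPCFRGCRLISCKRETARREASKLCAKRSVINETRHSGLLGTFGPTTIMEGKDAPTHGT
RWTNRYYRAAWAYGVALSHSKFLTGLITRPYISRCSLSKGLCDFRGTFVRALRSQLLRIRKFCVVAFTLG
SLRGKTFGKGIGVRPVVVVIVLIILSYERNEFRCHQRGFLRKDGCELGTKVSNASIRINCSRYHYTTIMG
LHQVREIVVDAPEPPSVCLNSLVAHWPPTNVTEKLRTIVNIWYAKSNSTLLIRPESSTICDRLRRALGTL
RKSKEHGSRALDNCTLLACLKVNRQSPLNRKIGLQTATRRLISDAIYIRTGSIRCLPWTIPEGIDEALER
KGISDVNQACFCKITLTSRNCVFSSAITRTSTISLSLKSMTGQDEVTGHNSGSPQGLPIHIKSYTEIDSS
ETNGEGSAILTVELGQCMWVLLLGSSIEDVSTDIARYTRWIHIRASDHLECETSIRKMHETAYTFTRTLY
YMQSIESRSHHLQSLFTQSDTGELPRRIFPTTGYAAIERGCLKVDALMIKISLSRAPETGPHVRCFGSRD
RTFQLYECILHVSKHDRPNQSCQWPRHTLATSACVSGICSPSCTISKLRQCLLIGHGMVRYKGYVIRDTH
LTPNKRQPSIYEDCKWGLSNRIATWVTGFRGRVYSARRELRKGTLRESHKPTRTLRLRFHRESWFMRGPR
GCYSRTACFIGKSVSARIEIYPNTGSDGYATSACSPRRPAYRRSWDPKSRSSGMQEPVGKGKKPRSICRA
EAYSSVEKAQPKTELVVRAAIRAELPEVATNKQMFSASRRTAESVTQTPFTLLRRRDYSQRRGQDITVTF
YYRYHDIRPNLCSSSASPKRRYGGCRVPADADYHPFPYVAGGLLLQEGSGLGTPFMSYQTRHSSIESSGS
VGYLWWPATRRQASIGTPLLPPLTFIPAIRKMLKVQQVSIIDPCRLRLNRLCFQRLESLYHTFLPRSIIP
GGGPLLERHSSPGGNCQLHSHSTTGAFRLRNIQATYRDISSTSIQRAVSKSQKALNGQRLRISCTRRCRW
RHIEAKMRCLMSALLPPCTRRYSVRCPLFHRVTLRRTADSHAWYQRNLSLRPLLFDCGKPMPEIASLNVE
LHPRSTAGAVGCCEEKLCPHHCALLYFVTSVIHGEPKVQIDKNPLASRFCYSFVRSLPTHKKVYRNFCPI
QPMAEDCVRLGWQKPLRLQPSPSVSCATTPMSKWTQPVLSQIGYQLPDAASVQLPDRGHYSVLSCATILQ
GNNYDGTSLSNTRIKIFLSSRQLAMSPRSQVLRSLHRATPRECLDSHDCFQAGIKWLNPRIIFKSQLGAK
RHPQAPSWVYQLFAKEHQESIILSEVVEQAHAFGQPGLRGRSSRFPGSSNGCGPGLQCHQNYAFYDLEQQ
LCNISASGHTSSASLVHEQLRSTSVICGRACGRLKTARVGKSYKIKFLTATGCLATDFEMNTGFFTTCTF
IDRQSNAFYLSVFGARTARPLWPDNPHSAKCRNMLETLLTRILQSVVCRFKDERTYDMVAFTQLRALLRA
VLQSIQVPWVSSCRGGRQSSLWNFRSYNRQVFSRVSVNPQSIGLLRGHRVLSGSPYGTKPIRAAWNQSRQ
VLLRRYGTCPRRRKDQIAIRLYNSRVFAPTCGPCTGCKGGFPHAHKSFTRPTRSATCDRSPVCSGKNSAY
FAVRRRRFQLLSPNFTASSYSAPAFPALYAQDPRARCSVRKSPWGLLDLLDQARKFFENTCYEANGIRAR
KSRSLIQPSLRVLPADLLEGLLLGRWLSGGPLSVMPGVPLGLQFGSNSGSDWDLNATLMYNTSSAVKVIE
PSRSAIQKTIEAVLVLKTCRRSGRYTCQFACTSPRVSDINRFDRVQGILVQEIIRSPLVTHSAVMLARWV
AVAPECRRSFLRSCLKKLLRSQYGLPWLSYFESLRLQSARNVANHSLCIELPGVDWGPNRRPKYLHSDCV
GPVCYYRPVTYHVSTCSPPSATRKCPREATPLILLRVGYYVPPHFVNSLPLGIRTINKSRSPGAGTNYAC
NVWASPPSSQGNHRATPWNPSPRDSGASEWMQRIIPVAKDVTRRSTSRLFIVTWRASIPGSGTKLSDRLG
TRVQAMIQPCARHTIQILYFHPVMRQGRMFILEARQDWRRRCLFASSTSCLKVRYRVQHHQISPSMPNSV
GEKDDAPEVSRPSDFGVRHLRSYLDITGNRPRKYTGLGWPAEQLPLSTLLVGSPHAANGPIVVVALSTFT
ACILSTHRRPSQQTRIGLLLRERCWAKSETKSASCHLVYSYSTRAECESYQIGEQLCSPLLRTFTKYESV
PCVKRHGLHKKGRRCQVGSIIHQEACRIDGGVSSDDRLGVTKVEDGVMAGDNRLKGAGRVAFKDIFNLPR
ILTCLSGTNSIPTSVYEAGRAHLLGSLYTRLRRGGVAAYEGKGCGGVRGRTTSAVPIIYEVHVNNLGSLL
LSTQDKVHDSIFTCTRQYSCHMRRTPPYGISSLFLPLDRHTAWYRTNLNTRAQSMHMPRLCSLWAHLTLE
PIYRTVREFSDTTPISRSSHPTSAFIGTSTSTDSVGPLPTPIRPSIDGSHTEPIRYLLFYTSKTEWDTTV
IRYPSDLGSSDGAGIRYSVTWTFMNASLDPDNLHSSSIPSSTTNRFQYIRSLNVASTPNSCFPVSTRVFP
VKRSTGPGKCGNATTGRASFCRGKDMSSFSIGSFRHLDVVSYFPADDARESQSQVHQGIAQSVLRIMAMK
YLSPRSSAFTGACARVILDDEAAGIGCAPSHHDDKWHGVSVYLYSQGQSGADRRYFPHRITCAPIILPAK
VAMRNALHVYRAPACQNTGTPKSMLGRCGPPVASWPSLHICVEIWPIWRSRVSLSRRQTHVSRRSSSCFC
VGELVYGQGVNLAGPGTTTQMNQLVVYPITVSKRNLVPRTSSTQIISYPVIIKGIDLGASLGSEHLGTAR
SHTWRLTQGHTYSSVKRETILPTGCFRLMIYYGKAVAICKYLGSTLPQEEIKSSHHAWIGTFSVLLVCTY
HGCLTEALEVRNTFFIHLKNLSNLYAVISCPRSGTRWESRSERPVFYIPLSNPTQPLQSEGDVSKLFLFR
QCVHGTASVTSTSSPLTQHCPNPEWNATLRNVARPTVVLIVHRIIPQRSWVKSFSTNAMQLSGLSLRTGV
VRFELIVALCLCADLLLASMPFFMALRLLWLDEVTDHRISEPYPYGLDSRPEVGVQESRKRSWLNTRQQT
GWILSRDAESPHWPDALLTTPVCHSGEMAGLTQDGPCGVPYVYVKFHEGPWSVSVRSREYDPSRDTVGPR
FILSQSTCLRSRMDSQITRNAGIRGEPVLNHAPLAAGIRIPYFSESSHGLTHSVVISASTGVTVEKGRRS
RLANGAIITAHLLVLLAVSKEFKDQHIGTEARLCNSMREPGDVSGVSSRRLSSE
>VGSC
MRREVKRLLYVVVEVLYLSFLETQASPRYNGHQVSLRVIGIIREKASSVQRISPRGRPGFLWYPVAACST
VHNRHPTFQLDGSWPSFIVGYTRTEIGIHLVADIVTVPLFRQRSAPVVMTTPAGEIVRCYLSYSSVPVRD
QNRTASGLIGGIKFVIFADDCISGLGRRGWAARDSNSPQCPGYDVDLYVCVRLEARTSALEGQTHHGFRM
VEGFIGGDCIKIKDLKERDPCRQGIRFINSSPRLGPKASIYARPPDCSETCLNCSRLIIFRYEMARMICT
PASMGCLLYSRPKLRLKPSPMTFYITPMGVHGPDTLQQMHPSAHTSLDKTVHETADLIPLIHVPPVGVSR
RYTLADIIGAHNLFYNARVAGTHRVELHTSHLRPIPPVSWCRISSSSEVVRHFFWSIPVHANEGRKVARA
HYYIAHLAITVTILFLSAVTPALKEPAGGGSLQVRGSIPTLPHSRHRSTHVFQTSHAHGNETAHISLRIT
APIQVKIEILLDDAIPEGRGVGPTRHLRRKATRGQVLTRGASFPEASAPQARPPSDSARRTHHWYLLKSW
GSCATGVSAFNIPLADGFKNDNYRIPGMLKSIPCAFGSYTTVGHERGRESLTLPRVTNPIWQGPACYKNP
HHRRRQPRGKHTQLNPSPRTYVSSKLLIHSTGIAVKADYGLSKLCAIIRFGVARAACLALTVGSPPVTLI
TQVRNRRRATFYLSRLKANREHIDPLIRPWLRLSLLVLVHVKFTRRRYGTCSTNSVANHHAYEGCVLVKS
RSEGEFDHDRKVRWSAQLRPDLINLLVNEHCRVLASIYRSLRCFTRVWRQAHTLCVLLSAKFLLTSLAQL
SSIDTTNIEEPIMRIPGQDSLFLLTVLDAPENEKYTQLVGGLWLSSIPHKSGKHHFCDAAKTDHTCIWSN
SAFSIRSTSCPLDPSEGWRGWRATLPLLRPSRFVSPNRAVDMGPYSVTDNKFFCLNSHTRSTSLAQRLPC
VTHEITSAPRDGSAAPPLNLEMRNTNHSVLTALLSRLQFCAPVGESAPLFRELCYRTQTTRCADHLQSCV
EAFQLPILIDNIWLEVESGMAMVELVKGFYVVNTVNPPPGNTQSQIVSDASVSTGVSIILRLGFYRALIP
SLRKIGSSSRLVSTSSARHTSYPIDCPATYVNCSHFCKSLAIILAIRFPSRAPFAGIVWNYLGLRMRIYK
CFIMMKKSKRISISEASQPIPSRLSYNLQRTGRLSMASRYLCGRMCPTLGFTRHPGRQPRENAKYSCIPI
FNQSQNGTRRSPRFDIVHLESQRIDPVPVRRAFSRMSPRSICVPYKRLPLKGQEVRKLFPLRSLCIRCPP
SQWVVGPSRLPARYQHGMIPGALHTLLMLILKNSRHLRLACLYHCYKLGCVVSHWKIPAHVEVSAADRSV
FWICGIDIRCPSMHRSIEILLLKLNCTPVETFGPGGSNCPRPLANISSYLKANVIPIEYLSFTIHQLILP
YEPLRRTRFFTTVPDLVSKIFIPTRRDIAQNWRYPIGLEGVPIYVWLKRADMHVSVRTTAIRSKLTDQIR
WENRFRCREVRTSFLNDTVSLSTDATTATWACSGLSASYHLDPRMSRIGRAQGAPSQRARSSNNSKMYTT
TRKLSILPARPLQDRGDQVSSTAGDAFSLRTFFLKPLGPSQANMYSKFDLGELMLQTCWAVFVISIQNPL
TTASHLFIITVYSTVADTVLGGRAATKSAKVKRPQARCSRQMVLRPESAPRTSAARLNKHPSLISSGELR
WKTQSTLGFTPVVLRVVARLFRSMPFFKSDGAGDHDDPSESYTCKSVPDEVSIIPRRLKSHYGLVTILTR
PRMNRTHSCASATLVAVYSVSGSSLRNACRLVLVAESPKHRLERLSCQIGMSKMSKARRSARRCRRRMAG
QERTGNAHTGLPLNRGRNKLTEQPLQNEPVAKPSASATRSSNVYGSLTLRDHVWTSGSDLIAYRMLTRPR
IVINHNWYGHFNTSSLTLVGDVETRTSLKARGPIGGDLTIWGSVRLGVNPAPFQCVLRRETSMTKSLNAT
CIALRYPAHLRLSRVVGQPLRGDAEKSGSNHTAIRRSATSLTTIRTPEGPFAHTISPAPHPPTATPETDL
>nAChR-beta1
MPGRGVVGLWPARESIRQRPNLMNIPICPDHCGGILLFVLRNMTSPRYSHALCMEHDSLIVIDNGSVIAT
LATDCSIFYVRQPMLEDLWTLRPGIDRFCRRGERRSMISGQIGIDYPGATPHIGLVPCLLFSLGCRGGQL
KDGYTEHGVLFSPLRGQCVESNTQRGRYLNDEFQRSRSVRFHPHCERGTNQELHGCPKVLLVVLFCHNKT
FTAGPNYSTSVTKSNLDTVSKSSGTQPGQWKKSTSAQPLLTSMNKTKRLRLLLMRAHNFLQMHLQEHIMN
HECTLPSCVTNCFPCYKSPALCPIPGIRVVVNELAAKGRAGDRSSVDGPFAPLEGLRPPMLFRKFNFLSE
GPHLLRLSDLYFIQSDLTTACPVEAFERVTGSQMIGTCVASPNRRDYSKRGTGVRRDLFHSTLRLKSRSV
VSANQGSVVACEAAGLDTVCRDRSACGQYGDRYQPSYLNERLGAMNARDSDNSNWRTANSLYSYRLYLRS
DRAVVRKSSD
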