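<?xml version="1.0" encoding="UTF-8"?>
<!-- dataset file, XML dialect -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="dataset">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="name" type="xs:string" minOccurs="0"/>
        <xs:element name="chain" minOccurs="0">
          <xs:simpleType>
            <xs:restriction base="xs:string">
              <!-- case-insensitive true/false accepted by the reader -->
              <xs:pattern value="[tT][rR][uU][eE]|[fF][aA][lL][sS][eE]"/>
            </xs:restriction>
          </xs:simpleType>
        </xs:element>
        <xs:element name="points">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="point" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="x" type="xs:double"/>
                    <xs:element name="y" type="xs:double"/>
                    <xs:element name="z" type="xs:double"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
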